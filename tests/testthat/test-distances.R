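metrics_with_oracle <- c("ED", "RD", "JD", "WD", "TD")

test_that("vectorised metrics match the naive double-loop oracle", {
  for (seed in 1:3) {
    X <- abs(random_dataset(5, 6, seed))  # nonnegative so JD uses plain PMFs
    for (m in metrics_with_oracle) {
      D <- feature_distance(X, m)$D
      expect_equal(D, naive_metric(X, m), tolerance = 1e-9,
                   info = paste(m, "seed", seed))
    }
    G <- geodesic_distance(X, k = 2)$D
    expect_equal(G, naive_geodesic(X, 2), tolerance = 1e-9,
                 info = paste("GD seed", seed))
  }
})

test_that("all metrics satisfy symmetry, zero diagonal, nonnegativity", {
  X <- random_dataset(7, 8, 11)
  for (m in c(metrics_with_oracle, "GD")) {
    D <- feature_distance(X, m, k = 3)$D
    expect_true(all(is.finite(D)), info = m)
    expect_lt(max(abs(D - t(D))), 1e-9)
    expect_equal(unname(diag(D)), rep(0, 8), info = m)
    expect_true(all(D >= 0), info = m)
  }
})

test_that("metric ranges and invariances hold", {
  X <- random_dataset(10, 6, 3)
  expect_true(all(one_minus_correlation(X)$D <= 2 + 1e-12))
  expect_true(all(jensen_shannon_distance(abs(X))$D <= 1 + 1e-12))
  # sample reordering leaves every metric unchanged
  Xp <- X[sample(nrow(X)), ]
  for (m in c("ED", "RD", "WD", "TD")) {
    expect_equal(feature_distance(X, m)$D, feature_distance(Xp, m)$D,
                 tolerance = 1e-9, info = m)
  }
  expect_equal(geodesic_distance(X, 2)$D, geodesic_distance(Xp, 2)$D,
               tolerance = 1e-9)
  # tropical distance is invariant to adding a constant to any column
  Xs <- X; Xs[, 2] <- Xs[, 2] + 17.3
  expect_equal(tropical_distance(X)$D, tropical_distance(Xs)$D,
               tolerance = 1e-9)
})

test_that("hand-computed pairwise values are reproduced", {
  # 3-4-5 triangle over two samples
  X <- cbind(c(0, 0), c(3, 4))
  expect_equal(euclidean_distance(X)$D[1, 2], 5)
  # identical columns are at distance zero everywhere
  Xi <- cbind(c(1, 2, 3), c(1, 2, 3))
  expect_equal(euclidean_distance(Xi)$D[1, 2], 0)
  expect_equal(jensen_shannon_distance(Xi)$D[1, 2], 0)
  expect_equal(tropical_distance(Xi)$D[1, 2], 0)
  # perfectly linear features: correlation distance 0; negated: 2
  Xl <- cbind(c(1, 2, 3), c(2, 4, 6), -c(1, 2, 3))
  Drd <- one_minus_correlation(Xl)$D
  expect_equal(Drd[1, 2], 0)
  expect_equal(Drd[1, 3], 2)
  # JS of (0.5,0.5) vs (0.9,0.1), hand-evaluated via M = (0.7, 0.3)
  js_hand <- 0.5 * (0.5 * log2(0.5 / 0.7) + 0.5 * log2(0.5 / 0.3)) +
             0.5 * (0.9 * log2(0.9 / 0.7) + 0.1 * log2(0.1 / 0.3))
  expect_equal(jensen_shannon_distance(cbind(c(0.5, 0.5), c(0.9, 0.1)))$D[1, 2],
               js_hand, tolerance = 1e-12)
  # disjoint-support PMFs attain the base-2 JS maximum of 1
  expect_equal(jensen_shannon_distance(cbind(c(1, 0), c(0, 1)))$D[1, 2], 1)
  # WD order-statistic form: sorted (0,1) vs (2,5)
  expect_equal(wasserstein_distance(cbind(c(1, 0), c(2, 5)))$D[1, 2],
               sqrt((4 + 16) / 2))
  # WD is blind to within-column order; a constant shift moves it by |c|
  Xw <- cbind(c(3, 1, 2), c(2, 3, 1), c(3, 1, 2) + 4)
  Dw <- wasserstein_distance(Xw)$D
  expect_equal(Dw[1, 2], 0)
  expect_equal(Dw[1, 3], 4)
  # tropical: (1,2,3) vs (3,1,2) -> diffs (-2,1,1), range 3
  expect_equal(tropical_distance(cbind(c(1, 2, 3), c(3, 1, 2)))$D[1, 2], 3)
})

test_that("geodesic distance dominates Euclidean and handles chains", {
  # three collinear feature columns at Euclidean gaps 1, 1 with k = 1:
  # the end-to-end path must pass through the middle
  X <- rbind(c(0, 1, 2))
  X <- rbind(X, 0)  # two samples; distances driven by first row
  D <- geodesic_distance(X, k = 1)$D
  expect_equal(D[1, 3], 2)
  for (seed in 1:3) {
    Xr <- random_dataset(5, 8, seed + 20)
    Dg <- geodesic_distance(Xr, k = 2)$D
    De <- euclidean_distance(Xr)$D
    expect_true(all(Dg - De >= -1e-9), info = paste("seed", seed))
  }
  # fully connected regime collapses to Euclidean
  Xr <- random_dataset(5, 6, 31)
  expect_equal(geodesic_distance(Xr, k = 5)$D, euclidean_distance(Xr)$D,
               tolerance = 1e-9)
  expect_error(geodesic_distance(Xr, k = 6), "k must")
})

test_that("JD switches to softmax for signed data and flags all-zero columns", {
  X <- random_dataset(6, 4, 5)  # contains negatives -> softmax branch
  P <- apply(X, 2, function(c) { e <- exp(c - max(c)); e / sum(e) })
  expect_equal(jensen_shannon_distance(X)$D, naive_metric(P, "JD"),
               tolerance = 1e-9)
  X0 <- cbind(c(0, 0, 0), c(1, 2, 3))
  expect_warning(D0 <- jensen_shannon_distance(X0), "all-zero")
  expect_true(all(is.finite(D0$D)))
})

test_that("zero-variance features get correlation distance 1 with a warning", {
  X <- cbind(c(1, 1, 1, 1), rnorm(4), rnorm(4))
  expect_warning(D <- one_minus_correlation(X), "zero-variance")
  expect_equal(D$D[1, 2], 1)
  expect_equal(D$D[1, 1], 0)
})

test_that("Gaussian W2 closed form evaluates as printed", {
  expect_equal(gaussian_w2_closed_form(0, 0, 1, 1, 1), 0)
  expect_equal(gaussian_w2_closed_form(0, 1, 1, 1, 1), 1)
  expect_equal(gaussian_w2_closed_form(0, 0, 1, 2, 0), 1 + 4)
  expect_error(gaussian_w2_closed_form(0, 0, 1, 1, 1.5), "rho")
})
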