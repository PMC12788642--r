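# Simulators are exercised at reduced dimension (p = 200-300) to keep the
# suite fast; the structural checks do not depend on the noise-block width.

test_that("all generators honour the shape/label/determinism contract", {
  for (model in c("euclidean", "correlation", "geodesic", "js",
                  "wasserstein", "tropical")) {
    ds <- simulate_igtd_model(model, n = 50, p = 200, p_signal = 40, seed = 3)
    expect_equal(dim(ds$X), c(50L, 200L), info = model)
    expect_true(all(ds$y %in% 0:1), info = model)
    expect_true(all(is.finite(ds$X)), info = model)
    ds2 <- simulate_igtd_model(model, n = 50, p = 200, p_signal = 40, seed = 3)
    expect_identical(ds$X, ds2$X, info = model)
    expect_identical(ds$y, ds2$y, info = model)
    ds3 <- simulate_igtd_model(model, n = 50, p = 200, p_signal = 40, seed = 4)
    expect_false(identical(ds$X, ds3$X), info = model)
  }
})

test_that("euclidean model: signal variance 2, noise variance 1, logistic labels", {
  ds <- simulate_euclidean(n = 2000, p = 150, p_signal = 100, seed = 5)
  v_sig <- apply(ds$X[, 1:100], 2, var)
  v_noise <- apply(ds$X[, 101:150], 2, var)
  # chi-square concentration at n = 2000: sample variances within ~10%
  expect_true(all(abs(v_sig - 2) < 0.35))
  expect_true(all(abs(v_noise - 1) < 0.2))
  expect_equal(length(ds$meta$beta), 100L)
  # beta drawn around 2.5
  expect_lt(abs(mean(ds$meta$beta) - 2.5), 0.5)
})

test_that("correlation model: Toeplitz structure and the printed beta grid", {
  ds <- simulate_correlation(n = 5000, p = 120, p_signal = 100, seed = 6)
  expect_equal(ds$meta$beta, seq_len(100) / 100)  # (0.01, 0.02, ..., 1)
  C <- cor(ds$X[, 1:100])
  adj <- C[cbind(1:99, 2:100)]
  expect_lt(max(abs(adj - 0.95)), 0.02)       # adjacent columns at rho
  expect_lt(abs(C[1, 100]), 0.06)             # rho^99 ~ 0.006, near zero
})

test_that("geodesic model: balanced median split and isometric embedding", {
  ds <- simulate_geodesic(n = 100, p = 150, p_signal = 100, seed = 7)
  expect_equal(sum(ds$y), 50L)  # exact balance, ties to class 0
  # rotation preserves the 3-D point norms
  f <- ds$meta$f
  expect_equal(length(f), 100L)
  set.seed(7)
  t3 <- runif(100, 1.5 * pi, 4.5 * pi); h <- runif(100, 0, 21)
  norms3 <- t3^2 + h^2  # |(t cos t, h, t sin t)|^2
  expect_equal(unname(rowSums(ds$X[, 1:100]^2)), norms3, tolerance = 1e-9)
})

test_that("js model: simplex rows, equal means, class-0 rows more variable", {
  ds <- simulate_js(n = 2000, p = 150, p_signal = 100, seed = 8)
  sig <- ds$X[, 1:100]
  expect_true(all(abs(rowSums(sig) - 1) < 1e-9))
  expect_true(all(sig >= 0))
  # symmetric Dirichlet mean is 1/p for both classes
  expect_lt(max(abs(colMeans(sig[ds$y == 0, ]) - 0.01)), 0.004)
  expect_lt(max(abs(colMeans(sig[ds$y == 1, ]) - 0.01)), 0.004)
  # variance decreases with concentration: alpha0 = 0.1 rows are spikier
  v0 <- mean(apply(sig[ds$y == 0, ], 1, var))
  v1 <- mean(apply(sig[ds$y == 1, ], 1, var))
  expect_gt(v0, 3 * v1)
})

test_that("wasserstein model: sorted rows, W1 median split, template identity", {
  ds <- simulate_wasserstein(n = 100, p = 150, p_signal = 100, seed = 9)
  sig <- ds$X[, 1:100]
  expect_true(all(apply(sig, 1, function(r) all(diff(r) >= 0))))
  expect_equal(sum(ds$y), 50L)
  # the printed cumulative-sum W1 of the template against itself is zero
  Tmpl <- ds$meta$template
  expect_equal(sum(abs(cumsum(Tmpl - Tmpl))), 0)
  # recompute W1 from the stored template; must match the stored values
  w1 <- apply(sig, 1, function(x) sum(abs(cumsum(x - Tmpl))))
  expect_equal(unname(w1), unname(ds$meta$w1), tolerance = 1e-9)
  # generating label shifts the mean up by ~1
  expect_gt(mean(sig[ds$meta$y_generating == 1, ]) -
            mean(sig[ds$meta$y_generating == 0, ]), 0.7)
})

test_that("tropical model: centering, segment block structure, class shift", {
  ds <- simulate_tropical(n = 120, p = 150, p_signal = 100, seed = 10)
  sig <- ds$X[, 1:100]
  expect_lt(max(abs(colMeans(sig))), 1e-9)  # centering on by default
  seg <- ds$meta$segments
  # tropical distance within a segment is much smaller than between the
  # two shifted segments
  Dt <- tropical_distance(sig)$D
  same <- outer(seg, seg, "==") & upper.tri(Dt)
  cross_pm <- outer(seg == ds$meta$s_plus, seg == ds$meta$s_minus, "&")
  expect_gt(mean(Dt[cross_pm]) / mean(Dt[same]), 3)
  # uncentred construction: class-1 minus class-0 mean on s+ is ~ +delta
  ds2 <- simulate_tropical(n = 400, p = 120, p_signal = 100, seed = 12,
                           center_columns = FALSE)
  sp <- which(ds2$meta$segments == ds2$meta$s_plus)
  gap <- mean(ds2$X[ds2$y == 1, sp]) - mean(ds2$X[ds2$y == 0, sp])
  expect_lt(abs(gap - ds2$meta$delta), 0.1)
  # noise block is tight around zero (sigma 0.01)
  expect_lt(max(abs(ds$X[, 101:150])), 0.1)
})

test_that("noise columns are label-independent", {
  ds <- simulate_js(n = 1000, p = 140, p_signal = 100, seed = 13)
  pb <- abs(cor(ds$X[, 101:140], ds$y))
  expect_lt(max(pb), 0.12)  # point-biserial correlations near zero
})

test_that("parameter validation", {
  expect_error(simulate_tropical(n = 20, p = 30, p_signal = 10, S = 11),
               "segments")
  expect_error(simulate_igtd_model("js", n = 10, p = 5, p_signal = 10))
})
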