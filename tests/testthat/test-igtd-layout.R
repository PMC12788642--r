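test_that("rank_matrix assigns each rank once, symmetric, zero diagonal", {
  D <- matrix(c(0, 1, 3, 1, 0, 2, 3, 2, 0), 3, 3)  # d12 < d23 < d13
  R <- rank_matrix(D)
  expect_equal(R, matrix(c(0L, 1L, 3L, 1L, 0L, 2L, 3L, 2L, 0L), 3, 3))
  set.seed(2)
  Dr <- as.matrix(dist(matrix(rnorm(14), 7)))
  Rr <- rank_matrix(Dr)
  expect_equal(Rr, t(Rr))
  expect_equal(unname(diag(Rr)), rep(0L, 7))
  expect_equal(sort(Rr[lower.tri(Rr)]), seq_len(21L))
})

test_that("ties are broken by pair scan order", {
  D <- matrix(1, 3, 3); diag(D) <- 0  # all pairwise distances equal
  R <- rank_matrix(D)
  # scan order (2,1), (3,1), (3,2) receives ranks 1, 2, 3
  expect_equal(R[2, 1], 1L)
  expect_equal(R[3, 1], 2L)
  expect_equal(R[3, 2], 3L)
})

test_that("pixel rank matrix reflects grid geometry", {
  expect_equal(pixel_rank_matrix(c(1, 2))[1, 2], 1L)
  Q <- pixel_rank_matrix(c(2, 2))
  # 2x2 grid: four side pairs (distance 1) take ranks 1-4, the two
  # diagonal pairs (sqrt 2) take ranks 5-6
  side <- c(Q[1, 2], Q[1, 3], Q[2, 4], Q[3, 4])
  diag_ <- c(Q[1, 4], Q[2, 3])
  expect_setequal(side, 1:4)
  expect_setequal(diag_, 5:6)
  # transposing the grid is a pixel re-indexing, not a different geometry:
  # remapped pixel distances coincide, hence so do their ordinal ranks
  coords_d <- function(Nr, Nc) {
    pix <- seq_len(Nr * Nc) - 1L
    as.matrix(dist(cbind(pix %/% Nc, pix %% Nc)))
  }
  pix <- seq_len(6)
  r <- (pix - 1) %/% 3 + 1; cc <- (pix - 1) %% 3 + 1
  remap <- (cc - 1) * 2 + r  # (r,c) on 2x3 -> (c,r) on 3x2
  D23 <- coords_d(2, 3); D32 <- coords_d(3, 2)
  expect_equal(unname(D32[remap, remap]), unname(D23))
  # ordinal ranks may permute within a tie group under re-indexing, so
  # compare the rank sets per distance value rather than entry by entry
  Q23 <- pixel_rank_matrix(c(2, 3))
  Q32r <- pixel_rank_matrix(c(3, 2))[remap, remap]
  lt <- lower.tri(D23)
  split23 <- split(Q23[lt], D23[lt])
  split32 <- split(Q32r[lt], D23[lt])
  for (g in names(split23)) expect_setequal(split32[[g]], split23[[g]])
})

test_that("igtd_error sums squared lower-triangle rank differences", {
  R <- matrix(0L, 3, 3); Q <- matrix(0L, 3, 3)
  R[lower.tri(R)] <- c(1L, 2L, 3L); R <- R + t(R)
  Q[lower.tri(Q)] <- c(3L, 2L, 1L); Q <- Q + t(Q)
  expect_equal(igtd_error(R, Q), 8)
  expect_equal(igtd_error(R, R), 0)
  expect_error(igtd_error(R, matrix(0L, 2, 2)), "shape")
})

test_that("optimizer is a no-op on an already matching instance", {
  Q <- pixel_rank_matrix(c(2, 3))
  lay <- optimize_layout(Q, Q)
  expect_equal(lay$feature_to_pixel, 1:6)
  expect_equal(lay$error_trace, 0)
  expect_equal(lay$error, 0)
})

test_that("optimizer undoes a planted transposition", {
  Q <- pixel_rank_matrix(c(2, 2))
  perm <- c(1L, 3L, 2L, 4L)
  R <- Q[perm, perm]
  lay <- optimize_layout(R, Q)
  expect_equal(lay$error, 0)
  expect_lte(length(lay$error_trace), 3)  # solved within two accepted swaps
  expect_equal(R[lay$pixel_to_feature, lay$pixel_to_feature], Q)
})

test_that("optimizer matches or approaches the brute-force optimum (p <= 5)", {
  for (seed in 1:4) {
    set.seed(seed)
    D <- as.matrix(dist(matrix(rnorm(10), 5)))
    R <- rank_matrix(D)
    Q <- pixel_rank_matrix(c(1, 5))
    lay <- optimize_layout(R, Q)
    opt <- brute_force_layout(R, Q)
    expect_gte(lay$error, opt)             # never beats the global optimum
    expect_lte(lay$error, lay$error_trace[1])
    expect_true(all(diff(lay$error_trace) < 0))  # strict improvement only
    # the reachable optimum is invariant to pre-shuffling the features
    sh <- sample(5)
    expect_equal(brute_force_layout(R[sh, sh], Q), opt)
  }
})

test_that("incremental swap scoring equals full recomputation", {
  for (rep_i in 1:25) {
    set.seed(rep_i)
    p <- sample(4:8, 1)
    R <- rank_matrix(as.matrix(dist(matrix(rnorm(2 * p), p))))
    Q <- pixel_rank_matrix(c(1, p))
    perm <- sample(p)
    ab <- sample(p, 2)
    delta <- swap_error_delta(R, Q, perm, ab[1], ab[2])
    perm2 <- perm; perm2[ab] <- perm2[rev(ab)]
    full <- igtd_error(R[perm2, perm2], Q) - igtd_error(R[perm, perm], Q)
    expect_identical(delta, full)
  }
})

test_that("optimizer is deterministic and its trace non-increasing", {
  set.seed(9)
  D <- as.matrix(dist(matrix(rnorm(32), 16)))
  R <- rank_matrix(D)
  Q <- pixel_rank_matrix(c(4, 4))
  l1 <- optimize_layout(R, Q)
  l2 <- optimize_layout(R, Q)
  expect_identical(l1$feature_to_pixel, l2$feature_to_pixel)
  expect_identical(l1$error_trace, l2$error_trace)
  expect_true(all(diff(l1$error_trace) <= 0))
  expect_equal(l1$error, igtd_error(R[l1$pixel_to_feature, l1$pixel_to_feature], Q))
})

test_that("apply_layout scales per feature and round-trips exactly", {
  set.seed(4)
  X <- matrix(rnorm(7 * 12), 7, 12)
  X[, 5] <- 3  # constant feature maps to 0.5
  lay <- igtd_layout(euclidean_distance(X), c(3, 4))
  imgs <- apply_layout(X, lay)
  expect_equal(dim(imgs$images), c(7L, 3L, 4L))
  expect_true(all(imgs$images >= 0 & imgs$images <= 1))
  L <- imgs$layout
  const_pix <- which(L$pixel_to_feature == 5)
  r <- (const_pix - 1) %/% 4 + 1; cc <- (const_pix - 1) %% 4 + 1
  expect_true(all(imgs$images[, r, cc] == 0.5))
  # invert: pixels -> features -> undo min-max scaling
  Xrec <- matrix(0, 7, 12)
  for (pos in 1:12) {
    f <- L$pixel_to_feature[pos]
    rr <- (pos - 1) %/% 4 + 1; ccc <- (pos - 1) %% 4 + 1
    rng <- L$scale_max[f] - L$scale_min[f]
    Xrec[, f] <- imgs$images[, rr, ccc] * ifelse(rng > 0, rng, 0) +
      ifelse(rng > 0, L$scale_min[f], 3)
  }
  expect_equal(Xrec, X, tolerance = 1e-9)
})

test_that("identity layout on a 1 x p grid reproduces the scaled row order", {
  X <- matrix(seq_len(12), 3, 4)
  lay <- structure(list(feature_to_pixel = 1:4, pixel_to_feature = 1:4,
                        grid = c(1L, 4L), error = 0, error_trace = 0,
                        settings = list()), class = "igtd_layout")
  imgs <- apply_layout(X, lay)
  scaled <- apply(X, 2, function(cc) (cc - min(cc)) / (max(cc) - min(cc)))
  expect_equal(imgs$images[2, 1, ], scaled[2, ])
  # identical rows give identical images
  X2 <- rbind(X[1, ], X[1, ], X)
  imgs2 <- apply_layout(X2, lay)
  expect_equal(imgs2$images[1, , ], imgs2$images[2, , ])
})

test_that("grid mismatch errors instead of padding", {
  X <- matrix(rnorm(10 * 6), 10, 6)
  lay <- igtd_layout(euclidean_distance(X), c(2, 3))
  expect_error(apply_layout(X[, 1:5], lay), "does not match")
  expect_error(igtd_layout(euclidean_distance(X), c(2, 2)), "does not hold")
  expect_error(igtd_convert(matrix(rnorm(10 * 5), 10, 5)), "perfect square")
})
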