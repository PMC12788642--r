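#' Rank matrix of pairwise distances
#'
#' Ranks the `p(p-1)/2` lower-triangle distances ascending, assigning each
#' rank exactly once (ordinal ranking; ties are broken by pair scan order,
#' row-major over pairs `i > j`), and symmetrises the result with a zero
#' diagonal.  With this convention the rank matrix is a bijection onto
#' `1..p(p-1)/2` and the layout error is integer-valued.
#'
#' @param D An `igtd_dist` or a symmetric numeric matrix.
#' @return An integer p x p matrix of ranks.
#' @export
rank_matrix <- function(D) {
  if (inherits(D, "igtd_dist")) D <- D$D
  D <- as.matrix(D)
  p <- nrow(D)
  stopifnot(p == ncol(D), p >= 2L)
  # extract pairs (i > j) in row-major order: t(D)[upper.tri] scans
  # (2,1),(3,1),(3,2),(4,1),... which is the documented tie-break order
  vals <- t(D)[upper.tri(D)]
  r <- rank(vals, ties.method = "first")
  tmp <- matrix(0L, p, p)
  tmp[upper.tri(tmp)] <- as.integer(r)
  tmp + t(tmp)
}

#' Pixel distance rank matrix of an image grid
#'
#' Pixels are indexed row-major on the `Nr x Nc` grid; Euclidean distances
#' between their integer coordinates are ranked as in [rank_matrix()].  The
#' pixel grid is always Euclidean regardless of the feature metric: the
#' target representation is a flat image.
#'
#' @param grid_shape Integer vector `c(Nr, Nc)`.
#' @return An integer `(Nr*Nc) x (Nr*Nc)` rank matrix.
#' @export
pixel_rank_matrix <- function(grid_shape) {
  Nr <- as.integer(grid_shape[1L])
  Nc <- as.integer(grid_shape[2L])
  stopifnot(Nr >= 1L, Nc >= 1L, Nr * Nc >= 2L)
  pix <- seq_len(Nr * Nc) - 1L
  coords <- cbind(pix %/% Nc, pix %% Nc)
  rank_matrix(as.matrix(stats::dist(coords)))
}

#' Layout error between feature and pixel rank matrices
#'
#' The objective minimised by the layout optimiser: the lower-triangle sum
#' of squared rank differences \eqn{\sum_{i>j} (r_{ij} - q_{ij})^2}.
#'
#' @param R,Q Same-shape rank matrices.
#' @return A nonnegative scalar.
#' @export
igtd_error <- function(R, Q) {
  if (!all(dim(R) == dim(Q))) stop("R and Q must have the same shape")
  sum((R[lower.tri(R)] - Q[lower.tri(Q)])^2)
}

#' Optimise the feature-to-pixel assignment by pairwise swaps
#'
#' Greedy swap search: at each iteration the grid position with the largest
#' error contribution (among positions not selected within the last
#' `cooldown` iterations) is chosen, swapping it against every other
#' position is scored with an O(p) incremental update, and the best strictly
#' improving swap is applied (ties broken by the smallest partner index).
#' The search stops after `max_steps` iterations or `stall_limit`
#' consecutive iterations without improvement.  The procedure is
#' deterministic given its inputs.
#'
#' @param R Feature distance rank matrix.
#' @param Q Pixel distance rank matrix (same shape).
#' @param max_steps Iteration budget (default 3000).
#' @param stall_limit Consecutive non-improving iterations tolerated
#'   (default 200).
#' @param cooldown Iterations a position stays ineligible after selection;
#'   default `floor(p/2)`.
#' @param grid_shape Optional `c(Nr, Nc)` recorded in the layout.
#' @param seed Recorded in the layout for provenance; the search itself is
#'   deterministic.
#' @return An `igtd_layout`: `feature_to_pixel` and `pixel_to_feature`
#'   permutations, `grid`, `error` and the non-increasing `error_trace`
#'   (initial error first, then the error after each accepted swap).
#' @export
optimize_layout <- function(R, Q, max_steps = 3000, stall_limit = 200,
                            cooldown = NULL, grid_shape = NULL, seed = 1L) {
  if (!all(dim(R) == dim(Q))) stop("R and Q must have the same shape")
  p <- nrow(R)
  if (is.null(cooldown)) cooldown <- max(1L, p %/% 2L)
  storage.mode(R) <- "integer"
  storage.mode(Q) <- "integer"
  res <- igtd_optimize_cpp(R, Q, as.integer(max_steps),
                           as.integer(stall_limit), as.integer(cooldown))
  pixel_to_feature <- res$perm
  feature_to_pixel <- order(pixel_to_feature)
  structure(list(feature_to_pixel = feature_to_pixel,
                 pixel_to_feature = pixel_to_feature,
                 grid = if (is.null(grid_shape)) NULL else as.integer(grid_shape),
                 error = res$error,
                 error_trace = res$error_trace,
                 settings = list(max_steps = max_steps,
                                 stall_limit = stall_limit,
                                 cooldown = cooldown, seed = seed)),
            class = "igtd_layout")
}

#' @export
print.igtd_layout <- function(x, ...) {
  cat(sprintf("igtd_layout: %d features", length(x$feature_to_pixel)))
  if (!is.null(x$grid)) cat(sprintf(" on a %dx%d grid", x$grid[1], x$grid[2]))
  cat(sprintf("; err %.0f -> %.0f (%d accepted swaps)\n",
              x$error_trace[1], x$error, length(x$error_trace) - 1L))
  invisible(x)
}

#' Fit an IGTD layout from a distance matrix
#'
#' Convenience wrapper: builds the feature rank matrix from `D`, the pixel
#' rank matrix for `grid_shape`, and runs [optimize_layout()].
#'
#' @inheritParams optimize_layout
#' @param D An `igtd_dist` (or distance matrix) over the features.
#' @param grid_shape `c(Nr, Nc)` with `Nr * Nc` equal to the feature count.
#' @return An `igtd_layout`.
#' @export
igtd_layout <- function(D, grid_shape, max_steps = 3000, stall_limit = 200,
                        cooldown = NULL, seed = 1L) {
  metric <- if (inherits(D, "igtd_dist")) D$metric else NA_character_
  Dm <- if (inherits(D, "igtd_dist")) D$D else as.matrix(D)
  if (prod(grid_shape) != nrow(Dm)) {
    stop("grid ", grid_shape[1], "x", grid_shape[2],
         " does not hold ", nrow(Dm), " features")
  }
  R <- rank_matrix(Dm)
  Q <- pixel_rank_matrix(grid_shape)
  lay <- optimize_layout(R, Q, max_steps = max_steps,
                         stall_limit = stall_limit, cooldown = cooldown,
                         grid_shape = grid_shape, seed = seed)
  lay$metric <- metric
  lay
}

#' Render per-sample pseudo-images from an optimised layout
#'
#' Each feature is min-max scaled to `[0, 1]` over the samples (constant
#' features map to 0.5) and written to its assigned pixel, producing one
#' grayscale image per sample.  The scaling parameters are recorded in the
#' returned object so the transformation is invertible.
#'
#' @param X An `igtd_dataset` or numeric matrix (samples x features).
#' @param layout An `igtd_layout` with a `grid` whose size equals the
#'   feature count.  No silent padding: a mismatch is an error.
#' @return An `igtd_images` object: `images` (array `n x Nr x Nc` with
#'   intensities in `[0, 1]`), labels `y` (if available), `sample_ids`, and
#'   the `layout` augmented with the per-feature `scale_min`/`scale_max`.
#' @export
apply_layout <- function(X, layout) {
  stopifnot(inherits(layout, "igtd_layout"))
  y <- NULL; ids <- NULL
  if (inherits(X, "igtd_dataset")) { y <- X$y; ids <- X$sample_ids; X <- X$X }
  X <- as.matrix(X)
  p <- ncol(X)
  if (is.null(layout$grid)) stop("layout has no grid shape")
  Nr <- layout$grid[1L]; Nc <- layout$grid[2L]
  if (Nr * Nc != p) {
    stop("layout grid ", Nr, "x", Nc, " does not match ", p, " features")
  }
  mins <- apply(X, 2L, min)
  maxs <- apply(X, 2L, max)
  rng <- maxs - mins
  S <- sweep(sweep(X, 2L, mins, "-"), 2L, ifelse(rng > 0, rng, 1), "/")
  S[, rng == 0] <- 0.5
  Xpix <- S[, layout$pixel_to_feature, drop = FALSE]  # columns in pixel order
  # pixel index is row-major; reorder columns so array() fills r fastest
  rowmajor <- as.vector(matrix(seq_len(p), Nr, Nc, byrow = TRUE))
  imgs <- array(Xpix[, rowmajor], dim = c(nrow(X), Nr, Nc))
  layout$scale_min <- mins
  layout$scale_max <- maxs
  structure(list(images = imgs, y = y, sample_ids = ids, layout = layout),
            class = "igtd_images")
}

#' One-call tabular-to-image conversion
#'
#' Runs the full pipeline: feature distances under `metric`, rank matrices,
#' swap optimisation, image rendering.  The layout is fitted on the full
#' dataset without looking at labels, so it can be reused across
#' cross-validation folds without target leakage.
#'
#' @inheritParams feature_distance
#' @inheritParams optimize_layout
#' @param grid_shape `c(Nr, Nc)`; `NULL` picks the square grid when the
#'   feature count is a perfect square.
#' @return An `igtd_images` object (see [apply_layout()]).
#' @export
igtd_convert <- function(X, metric = "ED", grid_shape = NULL, k = 10,
                         max_steps = 3000, stall_limit = 200, seed = 1L) {
  p <- if (inherits(X, "igtd_dataset")) ncol(X$X) else ncol(X)
  if (is.null(grid_shape)) {
    s <- as.integer(round(sqrt(p)))
    if (s * s != p) stop("feature count ", p, " is not a perfect square; ",
                         "pass grid_shape explicitly")
    grid_shape <- c(s, s)
  }
  D <- feature_distance(X, metric, k = k)
  lay <- igtd_layout(D, grid_shape, max_steps = max_steps,
                     stall_limit = stall_limit, seed = seed)
  apply_layout(X, lay)
}

#' Expose the incremental swap-score used by the optimiser
#'
#' Returns the change in [igtd_error()] caused by swapping the features at
#' grid positions `a` and `b` under the permutation `pixel_to_feature`,
#' computed with the same O(p) update the optimiser uses internally.
#' Intended for verification against full recomputation.
#'
#' @param R,Q Rank matrices.
#' @param pixel_to_feature Current permutation (position -> feature).
#' @param a,b Grid positions to swap (1-based).
#' @return The scalar error change (negative = improvement).
#' @export
swap_error_delta <- function(R, Q, pixel_to_feature, a, b) {
  storage.mode(R) <- "integer"
  storage.mode(Q) <- "integer"
  igtd_swap_delta_cpp(R, Q, as.integer(pixel_to_feature),
                      as.integer(a), as.integer(b))
}
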