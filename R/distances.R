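#' Feature dissimilarity matrices for IGTD layouts
#'
#' Computes the p x p matrix of pairwise dissimilarities between the
#' *features* (columns) of a dataset under one of six metrics:
#'
#' * `ED` - Euclidean distance between feature columns.
#' * `RD` - one minus Pearson correlation, range `[0, 2]`.
#' * `GD` - geodesic distance: shortest paths along a symmetric
#'   k-nearest-neighbour graph over features with Euclidean edge weights
#'   (ISOMAP-style); disconnected components are bridged by single linkage.
#' * `JD` - Jensen-Shannon divergence (base-2 logs, range `[0, 1]`) between
#'   per-feature probability mass functions over the samples.
#' * `WD` - one-dimensional Wasserstein distance in its quantile form,
#'   computed from the sorted feature columns.
#' * `TD` - tropical (max-plus) distance: the range of coordinate-wise
#'   differences, invariant to additive shifts.
#'
#' @param X An `igtd_dataset` or a numeric samples-by-features matrix.
#' @param metric One of `"ED"`, `"RD"`, `"GD"`, `"JD"`, `"WD"`, `"TD"`.
#' @param k Neighbourhood size for the geodesic metric (default 10).
#' @param ... Passed to the individual metric functions.
#' @return An `igtd_dist` object: list with the symmetric matrix `D`
#'   (zero diagonal), `metric`, and `params`.
#' @export
feature_distance <- function(X, metric = c("ED", "RD", "GD", "JD", "WD", "TD"),
                             k = 10, ...) {
  metric <- match.arg(metric)
  switch(metric,
         ED = euclidean_distance(X),
         RD = one_minus_correlation(X),
         GD = geodesic_distance(X, k = k),
         JD = jensen_shannon_distance(X, ...),
         WD = wasserstein_distance(X),
         TD = tropical_distance(X))
}

as_feature_matrix <- function(X) {
  if (inherits(X, "igtd_dataset")) X <- X$X
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (!all(is.finite(X))) stop("input matrix contains non-finite values")
  if (ncol(X) < 2L) stop("at least two features are required")
  X
}

new_igtd_dist <- function(D, metric, params = list()) {
  dimnames(D) <- NULL
  diag(D) <- 0
  structure(list(D = D, metric = metric, params = params),
            class = "igtd_dist")
}

#' @export
print.igtd_dist <- function(x, ...) {
  cat(sprintf("igtd_dist: %s metric, %d features\n", x$metric, nrow(x$D)))
  invisible(x)
}

#' @rdname feature_distance
#' @export
euclidean_distance <- function(X) {
  X <- as_feature_matrix(X)
  D <- as.matrix(stats::dist(t(X)))
  new_igtd_dist(D, "ED")
}

#' @rdname feature_distance
#' @export
one_minus_correlation <- function(X) {
  X <- as_feature_matrix(X)
  sds <- apply(X, 2L, stats::sd)
  degenerate <- which(sds == 0)
  D <- suppressWarnings(1 - stats::cor(X))
  if (length(degenerate)) {
    # correlation with a constant column is undefined; fall back to the
    # uncorrelated value so downstream ranking stays finite
    warning(length(degenerate),
            " zero-variance feature(s); their correlation distance set to 1")
    D[degenerate, ] <- 1
    D[, degenerate] <- 1
  }
  D[D < 0] <- 0  # guard rounding below zero at perfect correlation
  new_igtd_dist(D, "RD")
}

# Symmetric kNN adjacency over the rows/cols of a distance matrix: an edge is
# kept when either endpoint lists the other among its k nearest.  Disconnected
# components are merged by repeatedly adding the single minimum-distance
# inter-component edge (single linkage) until one component remains.
knn_graph_distances <- function(Dfull, k, from = NULL) {
  p <- nrow(Dfull)
  if (k < 1 || k >= p) stop("k must satisfy 1 <= k < number of nodes")
  adj <- matrix(FALSE, p, p)
  for (i in seq_len(p)) {
    nb <- order(Dfull[i, -i])[seq_len(k)]
    nb <- seq_len(p)[-i][nb]
    adj[i, nb] <- TRUE
  }
  adj <- adj | t(adj)
  W <- Dfull * adj
  g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                           weighted = TRUE)
  comp <- igraph::components(g)
  n_bridges <- 0L
  while (comp$no > 1L) {
    memb <- comp$membership
    inter <- outer(memb, memb, "!=")
    Dm <- Dfull
    Dm[!inter] <- Inf
    idx <- arrayInd(which.min(Dm), dim(Dm))
    g <- igraph::add_edges(g, c(idx[1L], idx[2L]),
                           weight = Dfull[idx[1L], idx[2L]])
    n_bridges <- n_bridges + 1L
    comp <- igraph::components(g)
  }
  list(D = igraph::distances(g, v = from %||% igraph::V(g),
                             algorithm = "dijkstra"),
       n_bridges = n_bridges)
}

#' @rdname feature_distance
#' @export
geodesic_distance <- function(X, k = 10) {
  X <- as_feature_matrix(X)
  De <- as.matrix(stats::dist(t(X)))
  res <- knn_graph_distances(De, k)
  D <- res$D
  D <- (D + t(D)) / 2  # shortest paths are symmetric; average rounding noise
  new_igtd_dist(D, "GD", params = list(k = k, n_bridges = res$n_bridges))
}

# Per-column PMF over samples: plain normalisation for nonnegative data,
# softmax per column when any value in X is negative (e.g. z-scores).
feature_pmf <- function(X) {
  if (any(X < 0)) {
    P <- apply(X, 2L, function(col) {
      e <- exp(col - max(col))
      e / sum(e)
    })
  } else {
    cs <- colSums(X)
    zero <- which(cs == 0)
    if (length(zero)) {
      warning(length(zero),
              " all-zero feature column(s); using a uniform PMF for them")
      X[, zero] <- 1
      cs[zero] <- nrow(X)
    }
    P <- sweep(X, 2L, cs, "/")
  }
  P
}

#' @rdname feature_distance
#' @param sqrt_divergence If `TRUE` return the square root of the
#'   Jensen-Shannon divergence (the form that is a true metric).  The default
#'   `FALSE` returns the divergence itself, which is bounded in `[0, 1]`
#'   with base-2 logarithms.
#' @export
jensen_shannon_distance <- function(X, sqrt_divergence = FALSE) {
  X <- as_feature_matrix(X)
  P <- feature_pmf(X)
  D <- js_divergence_matrix_cpp(P)
  if (sqrt_divergence) D <- sqrt(D)
  new_igtd_dist(D, "JD", params = list(sqrt_divergence = sqrt_divergence))
}

#' @rdname feature_distance
#' @export
wasserstein_distance <- function(X) {
  X <- as_feature_matrix(X)
  n <- nrow(X)
  # quantile form: W2 between the empirical distributions of two columns is
  # the root mean square difference of their order statistics
  Xs <- apply(X, 2L, sort)
  D <- as.matrix(stats::dist(t(Xs))) / sqrt(n)
  new_igtd_dist(D, "WD")
}

#' @rdname feature_distance
#' @export
tropical_distance <- function(X) {
  X <- as_feature_matrix(X)
  D <- tropical_distance_matrix_cpp(X)
  new_igtd_dist(D, "TD")
}

#' Closed-form squared 2-Wasserstein distance between correlated Gaussians
#'
#' Returns \eqn{(\mu_X-\mu_Y)^2 + (\sigma_X-\sigma_Y)^2 +
#' 2\sigma_X\sigma_Y(1-\rho_{XY})}.  With \eqn{\rho_{XY}=1} this reduces to
#' the marginal Gaussian W2 and serves as the large-sample limit of the
#' empirical quantile form in [wasserstein_distance()] (whose sorting
#' corresponds to the comonotone coupling).
#'
#' @param mu_x,mu_y Means.
#' @param sigma_x,sigma_y Standard deviations (nonnegative).
#' @param rho Correlation in `[-1, 1]`.
#' @return The squared distance (a scalar).
#' @export
gaussian_w2_closed_form <- function(mu_x, mu_y, sigma_x, sigma_y, rho) {
  if (sigma_x < 0 || sigma_y < 0) stop("standard deviations must be >= 0")
  if (rho < -1 || rho > 1) stop("rho must lie in [-1, 1]")
  (mu_x - mu_y)^2 + (sigma_x - sigma_y)^2 + 2 * sigma_x * sigma_y * (1 - rho)
}
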