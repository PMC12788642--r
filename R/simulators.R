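#' Metric-aligned simulation models
#'
#' Six self-contained generators, each producing a binary-labelled
#' high-dimensional dataset whose discriminative structure is aligned with
#' one feature metric: `euclidean` (i.i.d. Gaussian signal, logistic
#' labels), `correlation` (Toeplitz-correlated Gaussian, monotone
#' coefficients), `geodesic` (Swiss-roll manifold, geodesic-threshold
#' labels), `js` (class-conditional Dirichlet compositions), `wasserstein`
#' (sorted-Gaussian quantile vectors with a W1 median split) and `tropical`
#' (segment-plateau vectors with class-dependent shifted segments).  In
#' every model the signal occupies the first `p_signal` columns; the
#' remaining columns are label-independent Gaussian noise.
#'
#' Defaults follow the study design the generators emulate: `n = 200`
#' samples, `p = 2500` total features, `p_signal = 100` signal features.
#'
#' @param model One of `"euclidean"`, `"correlation"`, `"geodesic"`,
#'   `"js"`, `"wasserstein"`, `"tropical"`.
#' @param n Number of samples.
#' @param p Total number of features (`>= p_signal`).
#' @param p_signal Number of structured signal features.
#' @param seed Integer seed; a given `(model, parameters, seed)` always
#'   reproduces the same dataset exactly.
#' @param ... Model-specific parameters passed through (see the individual
#'   generators).
#' @return An `igtd_dataset`; `meta` records the model name, the realised
#'   nuisance draws (coefficients, segment ids, ...) and all parameters.
#' @export
simulate_igtd_model <- function(model = c("euclidean", "correlation",
                                          "geodesic", "js", "wasserstein",
                                          "tropical"),
                                n = 200, p = 2500, p_signal = 100,
                                seed = 1L, ...) {
  model <- match.arg(model)
  fn <- switch(model,
               euclidean = simulate_euclidean,
               correlation = simulate_correlation,
               geodesic = simulate_geodesic,
               js = simulate_js,
               wasserstein = simulate_wasserstein,
               tropical = simulate_tropical)
  fn(n = n, p = p, p_signal = p_signal, seed = seed, ...)
}

#' Default simulation parameters
#'
#' @param model Model name as in [simulate_igtd_model()].
#' @param ... Overrides.
#' @return A named list of the generator's parameters.
#' @export
sim_spec <- function(model, ...) {
  base <- list(n = 200, p = 2500, p_signal = 100, seed = 1L)
  extra <- switch(model,
                  correlation = list(rho = 0.95, logit_scale = 3),
                  geodesic = list(knn_k = 10),
                  js = list(alpha0 = 0.1, alpha1 = 5),
                  tropical = list(S = 5, delta = 1.75, sigma_seg = 0.10,
                                  sigma_noise = 0.01, center_columns = TRUE),
                  list())
  utils::modifyList(c(base, extra, list(model = model)), list(...))
}

check_sim_args <- function(n, p, p_signal) {
  stopifnot(n >= 2, p_signal >= 1, p >= p_signal)
}

sim_names <- function(n, p, p_signal) {
  list(features = c(sprintf("sig%03d", seq_len(p_signal)),
                    if (p > p_signal)
                      sprintf("noise%04d", seq_len(p - p_signal))),
       samples = sprintf("S%03d", seq_len(n)))
}

noise_block <- function(n, p_noise, sd = 1) {
  if (p_noise == 0L) return(NULL)
  matrix(stats::rnorm(n * p_noise, sd = sd), n, p_noise)
}

#' @rdname simulate_igtd_model
#' @export
simulate_euclidean <- function(n = 200, p = 2500, p_signal = 100, seed = 1L) {
  check_sim_args(n, p, p_signal)
  set.seed(as.integer(seed))
  # signal block N(0, 2 I); coefficients drawn once per dataset from
  # N(2.5, 1) per component
  Xs <- matrix(stats::rnorm(n * p_signal, sd = sqrt(2)), n, p_signal)
  beta <- stats::rnorm(p_signal, mean = 2.5, sd = 1)
  prob <- stats::plogis(drop(Xs %*% beta))
  y <- stats::rbinom(n, 1L, prob)
  X <- cbind(Xs, noise_block(n, p - p_signal))
  nm <- sim_names(n, p, p_signal)
  colnames(X) <- nm$features
  new_igtd_dataset(X, y, sample_ids = nm$samples,
                   meta = list(model = "euclidean", beta = beta, seed = seed))
}

#' @rdname simulate_igtd_model
#' @param rho Toeplitz correlation parameter (default 0.95).
#' @param logit_scale Multiplier on the linear predictor (default 3).
#' @export
simulate_correlation <- function(n = 200, p = 2500, p_signal = 100,
                                 seed = 1L, rho = 0.95, logit_scale = 3) {
  check_sim_args(n, p, p_signal)
  set.seed(as.integer(seed))
  Sigma <- rho^abs(outer(seq_len(p_signal), seq_len(p_signal), "-"))
  Xs <- matrix(stats::rnorm(n * p_signal), n, p_signal) %*% chol(Sigma)
  beta <- seq_len(p_signal) / p_signal  # (1/100, 2/100, ..., 1)
  prob <- stats::plogis(logit_scale * drop(Xs %*% beta))
  y <- stats::rbinom(n, 1L, prob)
  X <- cbind(Xs, noise_block(n, p - p_signal))
  nm <- sim_names(n, p, p_signal)
  colnames(X) <- nm$features
  new_igtd_dataset(X, y, sample_ids = nm$samples,
                   meta = list(model = "correlation", beta = beta, rho = rho,
                               logit_scale = logit_scale, seed = seed))
}

#' @rdname simulate_igtd_model
#' @param knn_k Neighbourhood size of the sample graph used to compute the
#'   geodesic reference distance (default 10).
#' @export
simulate_geodesic <- function(n = 200, p = 2500, p_signal = 100, seed = 1L,
                              knn_k = 10) {
  check_sim_args(n, p, p_signal)
  if (p_signal < 3L) stop("geodesic model needs p_signal >= 3")
  set.seed(as.integer(seed))
  # classical Swiss roll: a 2-D sheet rolled up in 3-D
  t3 <- stats::runif(n, 1.5 * pi, 4.5 * pi)
  h <- stats::runif(n, 0, 21)
  P3 <- cbind(t3 * cos(t3), h, t3 * sin(t3))
  # isometric embedding into R^p_signal: zero-pad then rotate by a seeded
  # random orthogonal matrix (QR of a Gaussian matrix, positive diagonal)
  G <- matrix(stats::rnorm(p_signal * p_signal), p_signal, p_signal)
  qr_ <- qr(G)
  Qrot <- qr.Q(qr_) %*% diag(sign(diag(qr.R(qr_))))
  Xs <- cbind(P3, matrix(0, n, p_signal - 3L)) %*% Qrot
  # reference function: graph-geodesic distance from the first sample along
  # the symmetric kNN sample graph; label = above-median indicator
  Ds <- as.matrix(stats::dist(P3))
  f <- drop(knn_graph_distances(Ds, knn_k, from = 1L)$D)
  y <- as.integer(f > stats::median(f))  # ties fall to class 0
  X <- cbind(Xs, noise_block(n, p - p_signal))
  nm <- sim_names(n, p, p_signal)
  colnames(X) <- nm$features
  new_igtd_dataset(X, y, sample_ids = nm$samples,
                   meta = list(model = "geodesic", knn_k = knn_k,
                               f = f, seed = seed))
}

#' @rdname simulate_igtd_model
#' @param alpha0,alpha1 Symmetric Dirichlet concentrations for class 0
#'   (default 0.1, sparse spiky compositions) and class 1 (default 5,
#'   near-uniform compositions).
#' @export
simulate_js <- function(n = 200, p = 2500, p_signal = 100, seed = 1L,
                        alpha0 = 0.1, alpha1 = 5) {
  check_sim_args(n, p, p_signal)
  set.seed(as.integer(seed))
  y <- stats::rbinom(n, 1L, 0.5)
  alpha <- ifelse(y == 1L, alpha1, alpha0)
  # symmetric Dirichlet via normalised Gamma draws, one row at a time
  Xs <- t(vapply(alpha, function(a) {
    g <- stats::rgamma(p_signal, shape = a)
    if (sum(g) == 0) g <- rep(1, p_signal)  # guard underflow at tiny alpha
    g / sum(g)
  }, numeric(p_signal)))
  X <- cbind(Xs, noise_block(n, p - p_signal))
  nm <- sim_names(n, p, p_signal)
  colnames(X) <- nm$features
  new_igtd_dataset(X, y, sample_ids = nm$samples,
                   meta = list(model = "js", alpha0 = alpha0, alpha1 = alpha1,
                               seed = seed))
}

#' @rdname simulate_igtd_model
#' @export
simulate_wasserstein <- function(n = 200, p = 2500, p_signal = 100,
                                 seed = 1L) {
  check_sim_args(n, p, p_signal)
  set.seed(as.integer(seed))
  y_gen <- stats::rbinom(n, 1L, 0.5)
  if (all(y_gen == 1L)) {
    stop("no class-0 observations drawn; rerun with a different seed")
  }
  # each row is the sorted (quantile) vector of p_signal Gaussian draws,
  # N(0,1) for generating class 0 and N(1,1) for class 1
  Xs <- t(vapply(y_gen, function(cls) {
    sort(stats::rnorm(p_signal, mean = cls))
  }, numeric(p_signal)))
  template <- colMeans(Xs[y_gen == 0L, , drop = FALSE])
  w1 <- apply(Xs, 1L, function(x) sum(abs(cumsum(x - template))))
  y <- as.integer(w1 > stats::median(w1))  # ties fall to class 0
  X <- cbind(Xs, noise_block(n, p - p_signal))
  nm <- sim_names(n, p, p_signal)
  colnames(X) <- nm$features
  new_igtd_dataset(X, y, sample_ids = nm$samples,
                   meta = list(model = "wasserstein", y_generating = y_gen,
                               template = template, w1 = w1, seed = seed))
}

#' @rdname simulate_igtd_model
#' @param S Number of plateau segments (default 5).
#' @param delta Class-1 shift applied upward on one segment and downward on
#'   another; default 1.75, the midpoint of the design range `[1.5, 2]`.
#' @param sigma_seg Within-segment Gaussian jitter (default 0.10).
#' @param sigma_noise Standard deviation of the noise block (default 0.01).
#' @param center_columns Centre every signal column (default `TRUE`);
#'   removes the mean cues favoured by Euclidean/correlation metrics while
#'   leaving the tropical distance unchanged.
#' @export
simulate_tropical <- function(n = 200, p = 2500, p_signal = 100, seed = 1L,
                              S = 5, delta = 1.75, sigma_seg = 0.10,
                              sigma_noise = 0.01, center_columns = TRUE) {
  check_sim_args(n, p, p_signal)
  if (S > p_signal) stop("more segments than signal features")
  set.seed(as.integer(seed))
  # random partition of the signal indices into S near-equal segments:
  # shuffle, then cut into contiguous blocks
  shuffled <- sample.int(p_signal)
  sizes <- rep(p_signal %/% S, S) + (seq_len(S) <= p_signal %% S)
  seg_of <- integer(p_signal)
  seg_of[shuffled] <- rep(seq_len(S), sizes)
  spm <- sample.int(S, 2L)  # shifted segments, s+ then s-
  y <- stats::rbinom(n, 1L, 0.5)
  v <- matrix(stats::runif(n * S, -1, 1), n, S)  # per-sample segment levels
  shift <- matrix(0, n, S)
  shift[y == 1L, spm[1L]] <- delta
  shift[y == 1L, spm[2L]] <- -delta
  levels_ <- v + shift
  Xs <- levels_[, seg_of, drop = FALSE] +
    matrix(stats::rnorm(n * p_signal, sd = sigma_seg), n, p_signal)
  if (center_columns) Xs <- sweep(Xs, 2L, colMeans(Xs), "-")
  X <- cbind(Xs, noise_block(n, p - p_signal, sd = sigma_noise))
  nm <- sim_names(n, p, p_signal)
  colnames(X) <- nm$features
  new_igtd_dataset(X, y, sample_ids = nm$samples,
                   meta = list(model = "tropical", segments = seg_of,
                               s_plus = spm[1L], s_minus = spm[2L],
                               delta = delta, sigma_seg = sigma_seg,
                               sigma_noise = sigma_noise,
                               center_columns = center_columns, seed = seed))
}
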