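# Independent oracles used across the tests: deliberately naive scalar
# implementations, kept separate from the package's vectorised/compiled code.

naive_metric <- function(X, metric, k = 2) {
  p <- ncol(X); n <- nrow(X)
  D <- matrix(0, p, p)
  pair_fun <- switch(metric,
    ED = function(a, b) sqrt(sum((a - b)^2)),
    RD = function(a, b) 1 - stats::cor(a, b),
    WD = function(a, b) sqrt(mean((sort(a) - sort(b))^2)),
    TD = function(a, b) max(a - b) - min(a - b),
    JD = function(a, b) {
      pa <- a / sum(a); pb <- b / sum(b)
      m <- (pa + pb) / 2
      s <- 0
      for (t in seq_len(n)) {
        if (pa[t] > 0) s <- s + 0.5 * pa[t] * log2(pa[t] / m[t])
        if (pb[t] > 0) s <- s + 0.5 * pb[t] * log2(pb[t] / m[t])
      }
      s
    },
    stop("no naive form for ", metric))
  for (i in seq_len(p)) {
    for (j in seq_len(p)) {
      if (i != j) D[i, j] <- pair_fun(X[, i], X[, j])
    }
  }
  D
}

# Floyd-Warshall geodesic oracle on a symmetric kNN graph (dense recurrence)
naive_geodesic <- function(X, k) {
  p <- ncol(X)
  De <- as.matrix(stats::dist(t(X)))
  adj <- matrix(FALSE, p, p)
  for (i in seq_len(p)) {
    nb <- seq_len(p)[-i][order(De[i, -i])[seq_len(k)]]
    adj[i, nb] <- TRUE
  }
  adj <- adj | t(adj)
  G <- matrix(Inf, p, p)
  G[adj] <- De[adj]
  diag(G) <- 0
  for (m in seq_len(p)) G <- pmin(G, outer(G[, m], G[m, ], "+"))
  repeat {
    reach <- is.finite(G)
    comp_ok <- all(reach)
    if (comp_ok) break
    # single-linkage bridge: minimum Euclidean edge between components
    cand <- De
    cand[reach] <- Inf
    idx <- arrayInd(which.min(cand), dim(cand))
    G[idx[1], idx[2]] <- De[idx[1], idx[2]]
    G[idx[2], idx[1]] <- De[idx[1], idx[2]]
    # close under shortest paths before re-checking connectivity
    for (m in seq_len(p)) G <- pmin(G, outer(G[, m], G[m, ], "+"))
  }
  for (m in seq_len(p)) G <- pmin(G, outer(G[, m], G[m, ], "+"))
  G
}

all_permutations <- function(p) {
  if (p == 1L) return(list(1L))
  sub <- all_permutations(p - 1L)
  out <- vector("list", p * length(sub))
  r <- 0L
  for (s in sub) {
    for (pos in seq_len(p)) {
      r <- r + 1L
      out[[r]] <- append(s, p, after = pos - 1L)
    }
  }
  out
}

# exhaustive minimum of err(R', Q) over all p! feature permutations
brute_force_layout <- function(R, Q) {
  p <- nrow(R)
  best <- Inf
  for (perm in all_permutations(p)) {
    e <- sum((R[perm, perm][lower.tri(R)] - Q[lower.tri(Q)])^2)
    if (e < best) best <- e
  }
  best
}

random_dataset <- function(n, p, seed) {
  set.seed(seed)
  matrix(stats::rnorm(n * p), n, p)
}

# tiny linearly separable image fixture: class 0 dark, class 1 bright
separable_images <- function(n = 40, H = 12, W = 12, seed = 1) {
  set.seed(seed)
  y <- rep(0:1, length.out = n)
  A <- array(0, c(n, H, W))
  for (i in seq_len(n)) {
    A[i, , ] <- matrix(stats::runif(H * W, 0.6 * y[i], 0.4 + 0.6 * y[i]), H, W)
  }
  structure(list(images = A, y = y, sample_ids = sprintf("S%d", seq_len(n)),
                 layout = NULL),
            class = "igtd_images")
}
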