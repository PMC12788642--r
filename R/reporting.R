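#' Render a rank matrix as a grayscale heatmap PNG
#'
#' Linear grayscale map of the rank values; by default rank 1 is darkest and
#' the maximum rank lightest (`dark_small = TRUE`), so a well-ordered layout
#' shows a dark band along the diagonal.
#'
#' @param R A rank matrix (see [rank_matrix()]).
#' @param out Output PNG path.
#' @param dark_small Polarity flag; `FALSE` inverts the map.
#' @return `out`, invisibly.
#' @export
render_rank_heatmap <- function(R, out, dark_small = TRUE) {
  R <- as.matrix(R)
  img <- R / max(R)
  if (!dark_small) img <- 1 - img
  png::writePNG(img, out)
  invisible(out)
}

#' Class-wise pseudo-image panels
#'
#' Builds a two-row montage: the top row shows the representative (first by
#' index) class-0 sample, the bottom row the first class-1 sample, with one
#' column per image set (e.g. one per metric).  Written as a single
#' grayscale PNG with thin white separators.
#'
#' @param imgs An `igtd_images` object or a (optionally named) list of them;
#'   every set must contain both classes.
#' @param out Output PNG path.
#' @param gap Separator width in pixels (default 2).
#' @return `out`, invisibly.
#' @export
render_class_panels <- function(imgs, out, gap = 2L) {
  if (inherits(imgs, "igtd_images")) imgs <- list(imgs)
  panels <- lapply(imgs, function(s) {
    if (is.null(s$y) || length(unique(s$y)) < 2L) {
      stop("each image set must contain both classes")
    }
    list(s$images[which(s$y == 0L)[1L], , ],
         s$images[which(s$y == 1L)[1L], , ])
  })
  Nr <- nrow(panels[[1L]][[1L]]); Nc <- ncol(panels[[1L]][[1L]])
  ncols <- length(panels)
  H <- 2L * Nr + gap
  W <- ncols * Nc + (ncols - 1L) * gap
  canvas <- matrix(1, H, W)
  for (j in seq_len(ncols)) {
    c0 <- (j - 1L) * (Nc + gap)
    canvas[seq_len(Nr), c0 + seq_len(Nc)] <- panels[[j]][[1L]]
    canvas[Nr + gap + seq_len(Nr), c0 + seq_len(Nc)] <- panels[[j]][[2L]]
  }
  png::writePNG(canvas, out)
  invisible(out)
}

#' Simulate, convert and evaluate a grid of models x metrics
#'
#' For every requested (model, metric) cell: simulate the model's dataset,
#' fit the IGTD layout under the metric, render pseudo-images and run
#' repeated stratified k-fold cross-validation with the reference CNN.
#' Each model's dataset is simulated once and shared across its metrics,
#' and every cell's seeds derive deterministically from `seed`, so a cell
#' rerun in isolation reproduces its grid entry exactly.
#'
#' @param models Subset of the six model names (see
#'   [simulate_igtd_model()]).
#' @param metrics Subset of `c("ED","RD","GD","JD","WD","TD")`.
#' @param n,p,p_signal Dataset dimensions passed to the simulators.
#' @param grid_shape Image grid; `NULL` uses the square grid for `p`.
#' @param k Geodesic neighbourhood size.
#' @param spec A [cnn_spec()].
#' @param folds,repeats Cross-validation protocol (defaults 10 and 1).
#' @param max_steps,stall_limit Layout optimiser budget.
#' @param seed Master seed.
#' @return An `igtd_benchmark`: `table` (one row per cell with
#'   `"mean (sd)"` strings for the four indices), `reports` (named list of
#'   `igtd_cvreport`s) and `layouts`.
#' @export
run_benchmark <- function(models, metrics, n = 200, p = 2500, p_signal = 100,
                          grid_shape = NULL, k = 10, spec = cnn_spec(),
                          folds = 10L, repeats = 1L,
                          max_steps = 3000, stall_limit = 200, seed = 1L) {
  all_models <- c("euclidean", "correlation", "geodesic", "js",
                  "wasserstein", "tropical")
  all_metrics <- c("ED", "RD", "GD", "JD", "WD", "TD")
  stopifnot(all(models %in% all_models), all(metrics %in% all_metrics))
  reports <- list(); layouts <- list(); rows <- list()
  for (mi in seq_along(models)) {
    model <- models[mi]
    ds <- simulate_igtd_model(model, n = n, p = p, p_signal = p_signal,
                              seed = seed + match(model, all_models))
    for (metric in metrics) {
      cell <- paste(model, metric, sep = ".")
      imgs <- igtd_convert(ds, metric = metric, grid_shape = grid_shape,
                           k = k, max_steps = max_steps,
                           stall_limit = stall_limit, seed = seed)
      rep_ <- cross_validate(imgs, spec = spec, folds = folds,
                             repeats = repeats,
                             seed = seed + 100L * match(metric, all_metrics))
      reports[[cell]] <- rep_
      layouts[[cell]] <- imgs$layout
      s <- rep_$summary
      row <- data.frame(model = model, metric = metric,
                        stringsAsFactors = FALSE)
      for (i in seq_len(nrow(s))) {
        row[[s$index[i]]] <- s$formatted[i]
        row[[paste0(s$index[i], "_mean")]] <- s$mean[i]
      }
      rows[[cell]] <- row
    }
  }
  structure(list(table = do.call(rbind, c(rows, list(make.row.names = FALSE))),
                 reports = reports, layouts = layouts,
                 settings = list(n = n, p = p, p_signal = p_signal,
                                 folds = folds, repeats = repeats,
                                 seed = seed)),
            class = "igtd_benchmark")
}
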