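#' Reference CNN configuration
#'
#' Two convolutional blocks (3x3 kernels, stride 1, same padding, batch
#' normalisation, 2x2 max-pooling), a dense head and a sigmoid output
#' trained with binary cross-entropy and Adam.  Training monitors a held-out
#' validation split: the learning rate is halved after `lr_patience` epochs
#' without validation-loss improvement and training stops after
#' `es_patience` such epochs, restoring the best weights.
#'
#' @param filters Filter counts for the two conv blocks (default `c(32, 64)`).
#' @param dense_units Width of the dense head (default 64).
#' @param dropout Dropout rate after the dense head (default 0.25).
#' @param learning_rate Initial Adam learning rate (default 1e-3).
#' @param batch_size Minibatch size (default 16).
#' @param max_epochs Epoch budget (default 100; early stopping usually
#'   triggers well before).
#' @param lr_factor,lr_patience Learning-rate reduction factor and patience
#'   (defaults 0.5 and 5).
#' @param es_patience Early-stopping patience (default 10).
#' @param val_fraction Fraction of training data held out, stratified, as
#'   the monitored validation split (default 0.1).
#' @param bn_momentum Momentum of the batch-norm running statistics
#'   (default 0.9).
#' @return A `cnn_spec` list.
#' @export
cnn_spec <- function(filters = c(32L, 64L), dense_units = 64L,
                     dropout = 0.25, learning_rate = 1e-3,
                     batch_size = 16L, max_epochs = 100L,
                     lr_factor = 0.5, lr_patience = 5L,
                     es_patience = 10L, val_fraction = 0.1,
                     bn_momentum = 0.9) {
  stopifnot(length(filters) == 2L, lr_patience >= 1L, es_patience >= 1L,
            dropout >= 0, dropout < 1, max_epochs >= 1L)
  structure(list(filters = as.integer(filters),
                 dense_units = as.integer(dense_units),
                 dropout = dropout, learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 lr_factor = lr_factor, lr_patience = as.integer(lr_patience),
                 es_patience = as.integer(es_patience),
                 val_fraction = val_fraction, bn_momentum = bn_momentum),
            class = "cnn_spec")
}

# n x H x W array -> n x (H*W) matrix with row-major pixel columns
flatten_images <- function(A) {
  d <- dim(A)
  matrix(aperm(A, c(1L, 3L, 2L)), d[1L], d[2L] * d[3L])
}

#' Train the reference CNN once
#'
#' @param train_images,val_images Arrays `n x Nr x Nc` with intensities in
#'   `[0, 1]`; both must share one grid shape.
#' @param train_labels,val_labels Binary 0/1 vectors.
#' @param spec A [cnn_spec()].
#' @param seed Integer seed controlling weight initialisation, epoch
#'   shuffling and dropout; a fixed seed gives bit-identical fits.
#' @return An `igtd_cnn` handle supporting [predict_cnn()]; its
#'   `model$history` records per-epoch train/validation loss, the epochs
#'   run and the restored best epoch.
#' @export
train_once <- function(train_images, train_labels, val_images, val_labels,
                       spec = cnn_spec(), seed = 1L) {
  dtr <- dim(train_images); dva <- dim(val_images)
  if (!all(dtr[2:3] == dva[2:3])) stop("train and validation grids differ")
  if (length(unique(train_labels)) < 2L) {
    stop("training fold contains a single class; stratify the split")
  }
  cfg <- list(filters1 = spec$filters[1L], filters2 = spec$filters[2L],
              dense = spec$dense_units, dropout = spec$dropout,
              learning_rate = spec$learning_rate,
              batch_size = spec$batch_size, max_epochs = spec$max_epochs,
              lr_factor = spec$lr_factor, lr_patience = spec$lr_patience,
              es_patience = spec$es_patience, bn_momentum = spec$bn_momentum)
  model <- cnn_fit_cpp(flatten_images(train_images), as.numeric(train_labels),
                       flatten_images(val_images), as.numeric(val_labels),
                       dtr[2L], dtr[3L], cfg, as.integer(seed))
  structure(list(model = model, spec = spec, grid = dtr[2:3]),
            class = "igtd_cnn")
}

#' Predict class-1 probabilities from a fitted CNN
#'
#' @param fit An `igtd_cnn` from [train_once()].
#' @param images Array `n x Nr x Nc` on the grid the model was trained on.
#' @return Numeric vector of probabilities.
#' @export
predict_cnn <- function(fit, images) {
  stopifnot(inherits(fit, "igtd_cnn"))
  d <- dim(images)
  if (!all(d[2:3] == fit$grid)) stop("image grid does not match the model")
  as.numeric(cnn_predict_cpp(fit$model, flatten_images(images)))
}

#' Validation indices from confusion counts
#'
#' Accuracy, precision, recall and F1 from the four confusion counts.
#' Ratios with a zero denominator are reported as 0 and named in the
#' `undefined` element, so degenerate folds are visible rather than `NaN`.
#'
#' @param tp,fp,tn,fn Nonnegative confusion counts with a positive total.
#' @return List with `accuracy`, `precision`, `recall`, `f1` and
#'   `undefined` (character vector of flagged indices).
#' @export
compute_indices <- function(tp, fp, tn, fn) {
  counts <- c(tp, fp, tn, fn)
  if (any(counts < 0)) stop("confusion counts must be nonnegative")
  total <- sum(counts)
  if (total == 0) stop("confusion counts sum to zero")
  undef <- character()
  precision <- if (tp + fp > 0) tp / (tp + fp) else {
    undef <- c(undef, "precision"); 0
  }
  recall <- if (tp + fn > 0) tp / (tp + fn) else {
    undef <- c(undef, "recall"); 0
  }
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else {
    undef <- c(undef, "f1"); 0
  }
  list(accuracy = (tp + tn) / total, precision = precision,
       recall = recall, f1 = f1, undefined = undef)
}

# stratified fold assignment: shuffle indices within each class, deal them
# round-robin so every fold's class proportion is within one sample of the
# global proportion
stratified_folds <- function(y, folds) {
  fold_id <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    if (length(idx) < folds) {
      stop("class ", cls, " has fewer members (", length(idx),
           ") than folds (", folds, ")")
    }
    fold_id[sample(idx)] <- rep_len(seq_len(folds), length(idx))
  }
  fold_id
}

# stratified inner split of a training fold for callback monitoring
inner_split <- function(y, fraction) {
  val_idx <- integer()
  for (cls in unique(y)) {
    idx <- which(y == cls)
    n_val <- max(1L, round(fraction * length(idx)))
    val_idx <- c(val_idx, sample(idx, n_val))
  }
  sort(val_idx)
}

pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Repeated stratified k-fold cross-validation of pseudo-image classification
#'
#' For each repeat, samples are split into stratified folds; each fold is
#' held out in turn while the CNN trains on the rest (with a stratified
#' inner validation split of `spec$val_fraction` for the learning-rate and
#' early-stopping callbacks) and is then scored on the held-out fold at the
#' 0.5 probability threshold.  The layout producing `imgs` is expected to
#' have been fitted without labels, so no target information leaks into the
#' transform.
#'
#' @param imgs An `igtd_images` object with labels, or an array plus `y`.
#' @param spec A [cnn_spec()].
#' @param folds Number of folds (default 10).
#' @param repeats Number of repetitions of the whole k-fold cycle
#'   (default 1).
#' @param seed Integer seed; fold assignment and every fit derive from it.
#' @param y Labels, only needed when `imgs` is a bare array.
#' @return An `igtd_cvreport`: `folds` (per-fold confusion counts and
#'   indices), `summary` (mean, population sd and a `"mean (sd)"` string
#'   per index) and the settings used.
#' @export
cross_validate <- function(imgs, spec = cnn_spec(), folds = 10L,
                           repeats = 1L, seed = 1L, y = NULL) {
  if (inherits(imgs, "igtd_images")) {
    y <- imgs$y
    A <- imgs$images
  } else {
    A <- imgs
  }
  if (is.null(y)) stop("labels are required")
  y <- as.integer(y)
  n <- dim(A)[1L]
  stopifnot(length(y) == n, folds >= 2L)
  set.seed(as.integer(seed))
  rows <- vector("list", folds * repeats)
  r <- 0L
  for (rep_i in seq_len(repeats)) {
    fold_id <- stratified_folds(y, folds)
    for (f in seq_len(folds)) {
      test_idx <- which(fold_id == f)
      train_idx <- which(fold_id != f)
      val_rel <- inner_split(y[train_idx], spec$val_fraction)
      val_idx <- train_idx[val_rel]
      fit_idx <- setdiff(train_idx, val_idx)
      fit_seed <- sample.int(.Machine$integer.max, 1L)
      fit <- train_once(A[fit_idx, , , drop = FALSE], y[fit_idx],
                        A[val_idx, , , drop = FALSE], y[val_idx],
                        spec = spec, seed = fit_seed)
      prob <- predict_cnn(fit, A[test_idx, , , drop = FALSE])
      pred <- as.integer(prob >= 0.5)
      yt <- y[test_idx]
      tp <- sum(pred == 1L & yt == 1L); fp <- sum(pred == 1L & yt == 0L)
      tn <- sum(pred == 0L & yt == 0L); fn <- sum(pred == 0L & yt == 1L)
      vi <- compute_indices(tp, fp, tn, fn)
      r <- r + 1L
      rows[[r]] <- data.frame(repeat_ = rep_i, fold = f, n_test = length(yt),
                              tp = tp, fp = fp, tn = tn, fn = fn,
                              accuracy = vi$accuracy, precision = vi$precision,
                              recall = vi$recall, f1 = vi$f1,
                              epochs = fit$model$history$epochs_run)
    }
  }
  folds_df <- do.call(rbind, rows)
  idx_names <- c("accuracy", "precision", "recall", "f1")
  summary_df <- data.frame(
    index = idx_names,
    mean = vapply(idx_names, function(v) mean(folds_df[[v]]), 0),
    sd = vapply(idx_names, function(v) pop_sd(folds_df[[v]]), 0),
    row.names = NULL)
  summary_df$formatted <- sprintf("%.4f (%.4f)", summary_df$mean, summary_df$sd)
  structure(list(folds = folds_df, summary = summary_df,
                 settings = list(folds = folds, repeats = repeats,
                                 seed = seed, spec = spec)),
            class = "igtd_cvreport")
}

#' @export
print.igtd_cvreport <- function(x, ...) {
  cat(sprintf("igtd_cvreport: %d-fold CV x %d repeat(s)\n",
              x$settings$folds, x$settings$repeats))
  for (i in seq_len(nrow(x$summary))) {
    cat(sprintf("  %-9s %s\n", x$summary$index[i], x$summary$formatted[i]))
  }
  invisible(x)
}

#' Format one or more CV reports as a mean (sd) grid
#'
#' @param reports A single `igtd_cvreport` or a named list of them (e.g.
#'   one per metric).
#' @return A data frame with one row per report and one `"mean (sd)"`
#'   column per validation index.
#' @export
format_cv_table <- function(reports) {
  if (inherits(reports, "igtd_cvreport")) reports <- list(report = reports)
  out <- lapply(names(reports), function(nm) {
    s <- reports[[nm]]$summary
    stats_row <- as.list(s$formatted)
    names(stats_row) <- s$index
    cbind(data.frame(run = nm, stringsAsFactors = FALSE),
          as.data.frame(stats_row, stringsAsFactors = FALSE))
  })
  do.call(rbind, out)
}
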