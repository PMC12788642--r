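#' Read a delimited feature table with a binary label column
#'
#' Loads a samples-by-features table from CSV/TSV text into an
#' `igtd_dataset`: a numeric matrix `X` (one row per sample, columns in file
#' order), a 0/1 label vector `y`, and the feature/sample identifiers.  The
#' two observed label levels are mapped to `{0, 1}` in lexical order and the
#' mapping is reported via `message()`, so the encoding is deterministic
#' without user input.
#'
#' @param path Path to a delimited text file with a header row.
#' @param label_column Name of the column holding the class label.
#' @param delim Field delimiter. `NULL` (default) sniffs `,` vs tab vs `;`
#'   from the header line.
#' @param na_action `"error"` (default) rejects any missing/non-numeric
#'   feature cell, naming its row and column; `"impute_median"` replaces
#'   missing values by the per-feature median.
#' @param zscore If `TRUE`, z-score each feature column after loading.
#'   Off by default: distances are computed on raw values unless the user
#'   opts in.
#' @return An object of class `igtd_dataset` with elements `X`, `y`,
#'   `feature_names`, `sample_ids`, `label_levels` and `meta`.
#' @export
load_table <- function(path, label_column, delim = NULL,
                       na_action = c("error", "impute_median"),
                       zscore = FALSE) {
  na_action <- match.arg(na_action)
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(delim)) {
    header <- readLines(path, n = 1L)
    delim <- if (grepl("\t", header)) "\t"
             else if (grepl(";", header)) ";"
             else ","
  }
  df <- utils::read.table(path, header = TRUE, sep = delim,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (!label_column %in% names(df)) {
    stop("label column '", label_column, "' not present in ", path)
  }
  lab_raw <- as.character(df[[label_column]])
  levels_seen <- sort(unique(lab_raw))
  if (length(levels_seen) > 2L) {
    stop("label column has ", length(levels_seen),
         " levels; at most two are supported")
  }
  y <- as.integer(match(lab_raw, levels_seen) - 1L)
  message("label mapping: ",
          paste(levels_seen, seq_along(levels_seen) - 1L,
                sep = " -> ", collapse = ", "))

  feat <- df[, setdiff(names(df), label_column), drop = FALSE]
  Xl <- lapply(seq_along(feat), function(j) {
    col <- feat[[j]]
    if (is.character(col) || is.logical(col)) {
      suppressWarnings(col <- as.numeric(col))
    }
    col
  })
  X <- do.call(cbind, Xl)
  colnames(X) <- names(feat)
  if (anyNA(X)) {
    bad <- which(is.na(X), arr.ind = TRUE)
    if (na_action == "error") {
      stop("missing or non-numeric value at row ", bad[1L, 1L],
           ", feature '", colnames(X)[bad[1L, 2L]], "'")
    }
    for (j in unique(bad[, 2L])) {
      med <- stats::median(X[, j], na.rm = TRUE)
      X[is.na(X[, j]), j] <- med
    }
  }
  if (anyDuplicated(colnames(X))) stop("feature names must be unique")
  if (zscore) X <- scale(X)[, , drop = FALSE]

  new_igtd_dataset(X, y,
                   sample_ids = rownames(df) %||% sprintf("S%d", seq_len(nrow(X))),
                   label_levels = levels_seen,
                   meta = list(source = path, zscore = zscore))
}

#' Write an `igtd_dataset` back to delimited text
#'
#' Inverse of [load_table()]: features in column order plus a final label
#' column (original label levels restored when known).
#'
#' @param dataset An `igtd_dataset`.
#' @param path Output file path.
#' @param label_column Name for the label column (default `"label"`).
#' @param delim Field delimiter (default `","`).
#' @return `path`, invisibly.
#' @export
save_table <- function(dataset, path, label_column = "label", delim = ",") {
  stopifnot(inherits(dataset, "igtd_dataset"))
  lab <- dataset$y
  if (!is.null(dataset$label_levels) && length(dataset$label_levels) == 2L) {
    lab <- dataset$label_levels[dataset$y + 1L]
  }
  df <- as.data.frame(dataset$X, check.names = FALSE)
  df[[label_column]] <- lab
  utils::write.table(df, path, sep = delim, row.names = FALSE, quote = FALSE)
  invisible(path)
}

new_igtd_dataset <- function(X, y, sample_ids = NULL, label_levels = NULL,
                             meta = list()) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  y <- as.integer(y)
  stopifnot(length(y) == nrow(X), all(y %in% c(0L, 1L)))
  if (!all(is.finite(X))) stop("dataset contains non-finite values")
  if (is.null(colnames(X))) colnames(X) <- sprintf("F%d", seq_len(ncol(X)))
  if (is.null(sample_ids)) sample_ids <- sprintf("S%d", seq_len(nrow(X)))
  structure(list(X = X, y = y,
                 feature_names = colnames(X),
                 sample_ids = as.character(sample_ids),
                 label_levels = label_levels,
                 meta = meta),
            class = "igtd_dataset")
}

#' @export
print.igtd_dataset <- function(x, ...) {
  cat(sprintf("igtd_dataset: %d samples x %d features (class 1: %d/%d)\n",
              nrow(x$X), ncol(x$X), sum(x$y), length(x$y)))
  if (!is.null(x$meta$model)) cat("  simulated model:", x$meta$model, "\n")
  invisible(x)
}

#' Save a pseudo-image set to disk
#'
#' `png8` writes one 8-bit grayscale PNG per sample, mapping intensity
#' `i` in `[0, 1]` to `floor(255 * i + 0.5)` (round half up); `rds` writes a
#' single lossless array bundle for exact round-trips.  Both formats get a
#' JSON manifest linking file, sample id and label.
#'
#' @param imgs An `igtd_images` object (see [apply_layout()]).
#' @param dir Output directory (created if absent).
#' @param format `"png8"` or `"rds"`.
#' @return Path of the written JSON manifest.
#' @export
save_images <- function(imgs, dir, format = c("png8", "rds")) {
  format <- match.arg(format)
  stopifnot(inherits(imgs, "igtd_images"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  n <- dim(imgs$images)[1L]
  ids <- imgs$sample_ids %||% sprintf("S%d", seq_len(n))
  if (format == "png8") {
    files <- sprintf("%s.png", ids)
    for (i in seq_len(n)) {
      img <- imgs$images[i, , ]
      quant <- floor(255 * img + 0.5) / 255
      png::writePNG(quant, file.path(dir, files[i]))
    }
  } else {
    files <- rep("images.rds", n)
    saveRDS(list(images = imgs$images, y = imgs$y, sample_ids = ids,
                 layout = imgs$layout), file.path(dir, "images.rds"))
  }
  manifest <- list(format = format,
                   grid = dim(imgs$images)[2:3],
                   samples = data.frame(file = files, sample_id = ids,
                                        label = imgs$y,
                                        stringsAsFactors = FALSE))
  mpath <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA)
  mpath
}

#' Load a pseudo-image bundle written by [save_images()] with `format="rds"`
#'
#' @param path Path to the `images.rds` bundle (or its directory).
#' @return An `igtd_images` object.
#' @export
load_images <- function(path) {
  if (dir.exists(path)) path <- file.path(path, "images.rds")
  b <- readRDS(path)
  structure(list(images = b$images, y = b$y, sample_ids = b$sample_ids,
                 layout = b$layout),
            class = "igtd_images")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
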