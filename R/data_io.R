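#' Load a labeled CSV dataset
#'
#' Reads a header CSV, maps the label column to \{-1, +1\} (values equal to
#' `positive_label` become +1, everything else -1), and applies the
#' missing-value rule of the experimental protocol: cells matching a
#' missing token (empty, "?", "NA", "nan" by default) are filled with 0.
#' Any remaining non-numeric feature cell is a parse error naming the
#' offending row and column.
#'
#' @param path CSV file with a header row.
#' @param label_column name of the label column.
#' @param positive_label value mapped to +1 (the sick case).
#' @param missing_tokens character vector of cell values treated as missing.
#' @return A [labeled_table()].
#' @export
load_csv <- function(path, label_column, positive_label,
                     missing_tokens = c("", "?", "NA", "nan")) {
  if (!file.exists(path)) stop_invalid("file not found: ", path)
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         na.strings = NULL)
  if (!label_column %in% names(raw)) {
    stop_invalid("label column '", label_column, "' not found in ", path)
  }
  y <- ifelse(trimws(raw[[label_column]]) == as.character(positive_label), 1, -1)
  feats <- raw[setdiff(names(raw), label_column)]
  X <- matrix(0, nrow(raw), ncol(feats))
  for (j in seq_along(feats)) {
    cell <- trimws(feats[[j]])
    miss <- cell %in% missing_tokens
    val <- suppressWarnings(as.numeric(cell))
    bad <- which(!miss & is.na(val))
    if (length(bad) > 0) {
      stop_invalid("non-numeric value '", cell[bad[1]], "' at row ", bad[1],
                   ", column '", names(feats)[j], "'")
    }
    val[miss] <- 0
    X[, j] <- val
  }
  labeled_table(X, y, feature_names = names(feats))
}

#' Write a labeled table to CSV
#'
#' Inverse of [load_csv()] with labels written as -1/+1 in column `label`;
#' `NA` feature entries are written as empty cells.
#'
#' @param table a [labeled_table()].
#' @param path output file.
#' @export
save_csv <- function(table, path) {
  stopifnot(inherits(table, "labeled_table"))
  df <- as.data.frame(table$X)
  names(df) <- table$feature_names
  df$label <- table$y
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Split specification
#'
#' @param test_fraction fraction held out for testing (default 0.2, the
#'   protocol's 8:2 split).
#' @param seed integer seed.
#' @param stratified preserve the class ratio in both parts (default TRUE).
#' @return A `split_spec`.
#' @export
split_spec <- function(test_fraction = 0.2, seed = 1L, stratified = TRUE) {
  if (test_fraction <= 0 || test_fraction >= 1) {
    stop_invalid("test_fraction must be in (0, 1)")
  }
  structure(list(test_fraction = test_fraction, seed = as.integer(seed),
                 stratified = stratified),
            class = "split_spec")
}

#' Stratified train/test split
#'
#' Disjoint and exhaustive; with stratification each class contributes
#' `round(class_count * test_fraction)` test samples (capped so at least
#' one training sample per class remains), which maintains the class
#' distribution across the split. Identical seeds yield identical splits.
#'
#' @param table a [labeled_table()].
#' @param spec a [split_spec()].
#' @return List with elements `train` and `test` ([labeled_table()]s) and
#'   `test_idx` (the held-out row indices).
#' @export
split_table <- function(table, spec = split_spec()) {
  stopifnot(inherits(table, "labeled_table"), inherits(spec, "split_spec"))
  n <- nrow(table$X)
  test_idx <- with_seed(spec$seed, {
    if (spec$stratified) {
      if (length(unique(table$y)) < 2L) {
        stop_invalid("stratified split needs both classes present")
      }
      unlist(lapply(unique(table$y), function(cls) {
        idx <- which(table$y == cls)
        k <- min(round(length(idx) * spec$test_fraction), length(idx) - 1L)
        if (k > 0) sample(idx, k) else integer(0)
      }))
    } else {
      sample.int(n, max(1L, round(n * spec$test_fraction)))
    }
  })
  test_idx <- sort(test_idx)
  train_idx <- setdiff(seq_len(n), test_idx)
  subset_tab <- function(idx) {
    labeled_table(table$X[idx, , drop = FALSE], table$y[idx],
                  feature_names = table$feature_names)
  }
  list(train = subset_tab(train_idx), test = subset_tab(test_idx),
       test_idx = test_idx)
}

#' Z-score standardization (baseline preprocessing only)
#'
#' Opt-in transform for comparisons against conventional classifiers that
#' require scaled inputs; the polynomial network itself is fit on raw
#' (zero-filled) features.
#'
#' @param table a [labeled_table()].
#' @return The table with each feature column centered and scaled (constant
#'   columns are left centered at 0).
#' @export
standardize <- function(table) {
  stopifnot(inherits(table, "labeled_table"))
  X <- zero_fill(table)$X
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  sdv[sdv == 0] <- 1
  table$X <- sweep(sweep(X, 2, mu), 2, sdv, "/")
  table
}
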