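#' Labeled data table for binary classification
#'
#' Bundles a numeric feature matrix with labels in \{-1, +1\} and optional
#' per-sample weights (a probability distribution over samples, as used by
#' the boosting wrapper). Positive class (+1) is the sick case throughout.
#'
#' @param X numeric matrix, n samples by d features. `NA` entries are allowed
#'   and are zero-filled by the estimators at fit/predict time.
#' @param y numeric vector of length n with entries in \{-1, +1\}.
#' @param weights optional non-negative vector of length n summing to 1.
#' @param feature_names optional character vector of length d; defaults to
#'   the column names of `X` or `x1..xd`.
#' @return An object of class `labeled_table` with fields `X`, `y`,
#'   `weights`, `feature_names`.
#' @examples
#' tab <- labeled_table(matrix(rnorm(20), 10, 2), rep(c(-1, 1), 5))
#' @export
labeled_table <- function(X, y, weights = NULL, feature_names = NULL) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  y <- as.numeric(y)
  if (nrow(X) < 2L) stop_invalid("need at least 2 samples, got ", nrow(X))
  if (ncol(X) < 1L) stop_invalid("need at least 1 feature")
  if (length(y) != nrow(X)) {
    stop_invalid("length(y) = ", length(y), " does not match nrow(X) = ", nrow(X))
  }
  if (!all(y %in% c(-1, 1))) stop_invalid("labels must be -1 or +1")
  if (!is.null(weights)) {
    weights <- as.numeric(weights)
    if (length(weights) != nrow(X)) stop_invalid("weights length mismatch")
    if (any(weights < 0)) stop_invalid("weights must be non-negative")
    if (abs(sum(weights) - 1) > 1e-9) stop_invalid("weights must sum to 1")
  }
  if (is.null(feature_names)) {
    feature_names <- colnames(X) %||% paste0("x", seq_len(ncol(X)))
  }
  colnames(X) <- feature_names
  structure(
    list(X = X, y = y, weights = weights, feature_names = feature_names),
    class = "labeled_table"
  )
}

#' @export
print.labeled_table <- function(x, ...) {
  cat(sprintf(
    "labeled_table: %d samples x %d features (%d positive, %d negative)%s\n",
    nrow(x$X), ncol(x$X), sum(x$y == 1), sum(x$y == -1),
    if (is.null(x$weights)) "" else ", weighted"
  ))
  invisible(x)
}

#' Replace missing feature entries with zeros
#'
#' The experimental protocol fills missing cells with 0 before any model
#' sees the matrix; this applies that rule to a [labeled_table].
#'
#' @param table a [labeled_table].
#' @return The table with `NA` entries of `X` set to 0.
#' @export
zero_fill <- function(table) {
  stopifnot(inherits(table, "labeled_table"))
  table$X[is.na(table$X)] <- 0
  table
}

#' NLPNN configuration
#'
#' @param omega positive integer vector: per-layer width caps; its length M
#'   is the number of non-output layers. Default `rep(d + 1, 2)` is filled
#'   in at fit time when `NULL` (each layer has at most d+1 nodes).
#' @param lambda_grid positive reals: candidate regularization factors for
#'   the hinge readout. Default `10^(-3:1)`.
#' @param rank_tol relative tolerance for numerical-rank / linear-dependence
#'   decisions. Default `1e-8`.
#' @param seed integer seed; all fitting randomness derives from it.
#' @param epochs,batch_size,eta0 stochastic gradient descent settings for
#'   the readout: number of passes, mini-batch size, and initial step size
#'   of the staged geometric decay schedule (see [fit_readout()]);
#'   `eta0 = NULL` (default) scales the step with 1/lambda.
#' @param validation_fraction fraction of the training data held out
#'   (stratified) to pick the best (layer, lambda) pair. Default 0.2.
#' @return An object of class `nlpnn_config`.
#' @export
nlpnn_config <- function(omega = NULL,
                         lambda_grid = 10^(-3:1),
                         rank_tol = 1e-8,
                         seed = 1L,
                         epochs = 160L,
                         batch_size = 16L,
                         eta0 = NULL,
                         validation_fraction = 0.2) {
  if (!is.null(omega)) {
    omega <- as.integer(omega)
    if (length(omega) < 1L || any(omega < 1L)) {
      stop_invalid("omega must be a non-empty vector of widths >= 1")
    }
  }
  if (length(lambda_grid) < 1L || any(lambda_grid <= 0)) {
    stop_invalid("lambda_grid must be non-empty and positive")
  }
  if (rank_tol < 0) stop_invalid("rank_tol must be >= 0")
  if (validation_fraction <= 0 || validation_fraction >= 1) {
    stop_invalid("validation_fraction must be in (0, 1)")
  }
  structure(
    list(
      omega = omega, lambda_grid = sort(lambda_grid), rank_tol = rank_tol,
      seed = as.integer(seed), epochs = as.integer(epochs),
      batch_size = as.integer(batch_size), eta0 = eta0,
      validation_fraction = validation_fraction
    ),
    class = "nlpnn_config"
  )
}

# Resolve a NULL omega to the default (d+1, d+1) once d is known.
resolve_omega <- function(config, d) {
  if (is.null(config$omega)) config$omega <- rep(d + 1L, 2L)
  config
}
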