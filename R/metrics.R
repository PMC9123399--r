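#' Confusion matrix for binary labels
#'
#' Counts with +1 (the sick case) as the positive class.
#'
#' @param y_true,y_pred label vectors in \{-1, +1\}, equal length.
#' @return A `confusion_matrix`: list with integer fields TP, FP, TN, FN, N.
#' @export
confusion <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) stop_invalid("length mismatch")
  if (!all(c(y_true, y_pred) %in% c(-1, 1))) stop_invalid("labels must be -1/+1")
  tp <- sum(y_true == 1 & y_pred == 1)
  fp <- sum(y_true == -1 & y_pred == 1)
  tn <- sum(y_true == -1 & y_pred == -1)
  fn <- sum(y_true == 1 & y_pred == -1)
  structure(list(TP = tp, FP = fp, TN = tn, FN = fn, N = tp + fp + tn + fn),
            class = "confusion_matrix")
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUC with midranks for tied scores; invariant
#' under strictly monotone transforms of the scores.
#'
#' @param y_true labels in \{-1, +1\}.
#' @param scores real-valued decision scores (higher = more positive).
#' @return AUC in `[0, 1]`, or `NA` when one class is absent.
#' @export
auc_score <- function(y_true, scores) {
  if (length(y_true) != length(scores)) stop_invalid("length mismatch")
  n_pos <- sum(y_true == 1)
  n_neg <- sum(y_true == -1)
  if (n_pos == 0 || n_neg == 0) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[y_true == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Classification metrics report
#'
#' Computes accuracy, specificity, precision, recall, F1 (harmonic mean of
#' precision and recall, equivalently `2*TP / (N + TP - TN)`), G-mean
#' (`sqrt(recall * specificity)`, the imbalance-robust summary), and AUC
#' when scores are supplied. A metric whose denominator is zero is reported
#' as `NA` (missing), never as an error.
#'
#' @param cm a [confusion()] result.
#' @param scores optional decision scores for AUC.
#' @param y_true labels matching `scores` (required when scores given).
#' @return A `metric_report`: named list of reals in `[0, 1]` (or `NA`).
#' @examples
#' cm <- structure(list(TP = 25, FP = 5, TN = 60, FN = 10, N = 100),
#'                 class = "confusion_matrix")
#' metric_report(cm)$g_mean
#' @export
metric_report <- function(cm, scores = NULL, y_true = NULL) {
  stopifnot(inherits(cm, "confusion_matrix"))
  if (cm$N < 1) stop_invalid("empty confusion matrix")
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  accuracy <- ratio(cm$TP + cm$TN, cm$N)
  specificity <- ratio(cm$TN, cm$TN + cm$FP)
  precision <- ratio(cm$TP, cm$TP + cm$FP)
  recall <- ratio(cm$TP, cm$TP + cm$FN)
  f1 <- ratio(2 * cm$TP, 2 * cm$TP + cm$FP + cm$FN)
  g_mean <- if (is.na(recall) || is.na(specificity)) NA_real_ else {
    sqrt(recall * specificity)
  }
  auc <- if (!is.null(scores)) {
    if (is.null(y_true)) stop_invalid("y_true required for AUC")
    auc_score(y_true, scores)
  } else {
    NA_real_
  }
  structure(
    list(accuracy = accuracy, specificity = specificity, precision = precision,
         recall = recall, f1 = f1, g_mean = g_mean, auc = auc),
    class = "metric_report"
  )
}

#' @export
print.metric_report <- function(x, ...) {
  vals <- unlist(x)
  cat("metric_report:\n")
  for (k in names(vals)) {
    cat(sprintf("  %-12s %s\n", k,
                if (is.na(vals[k])) "NA" else sprintf("%.4f", vals[k])))
  }
  invisible(x)
}

#' Evaluate a fitted model on a labeled table
#'
#' Convenience wrapper: predicts, builds the confusion matrix and returns
#' the full [metric_report()] including AUC from the decision scores.
#'
#' @param model an `nlpnn_model` or `aepnn_model`.
#' @param table a [labeled_table()].
#' @param ... passed to the score function (e.g. `L` for ensembles).
#' @return A `metric_report`.
#' @export
evaluate_model <- function(model, table, ...) {
  table <- zero_fill(table)
  scores <- if (inherits(model, "aepnn_model")) {
    aepnn_score(model, table$X, ...)
  } else {
    nlpnn_score(model, table$X, ...)
  }
  cm <- confusion(table$y, sign_pos(scores))
  metric_report(cm, scores = scores, y_true = table$y)
}
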