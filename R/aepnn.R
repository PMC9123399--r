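#' Vote weight of a base classifier
#'
#' The exponential loss of a weighted base classifier is minimized at
#' `alpha = 0.5 * log((1 - epsilon) / epsilon)`, where `epsilon` is the
#' classifier's weighted training error. Strictly decreasing in epsilon;
#' positive exactly when epsilon < 0.5.
#'
#' @param epsilon weighted error in (0, 1).
#' @return The vote weight alpha.
#' @export
classifier_weight <- function(epsilon) {
  if (any(epsilon <= 0 | epsilon >= 1)) stop_invalid("epsilon must be in (0, 1)")
  0.5 * log((1 - epsilon) / epsilon)
}

#' Weighted 0-1 error
#'
#' @param D_l distribution over samples (non-negative, sums to 1).
#' @param y,preds label vectors in \{-1, +1\}.
#' @return `sum(D_l * (y != preds))`.
#' @export
weighted_error <- function(D_l, y, preds) {
  if (length(D_l) != length(y) || length(y) != length(preds)) {
    stop_invalid("D_l, y, preds must have equal length")
  }
  sum(D_l * (y != preds))
}

#' Exponential-loss sample-weight update
#'
#' Multiplies each weight by `exp(-alpha * y_i * pred_i)` and renormalizes:
#' misclassified samples gain relative weight whenever `alpha > 0`, which is
#' how the next base learner's attention is steered toward them.
#'
#' @param D_l current distribution over samples.
#' @param alpha_l finite vote weight of the round's classifier.
#' @param y,preds true and predicted labels in \{-1, +1\}.
#' @return A `boost_state`: list with the new distribution `D` and the
#'   normalization constant `Z` (the pre-normalization sum).
#' @export
update_weights <- function(D_l, alpha_l, y, preds) {
  if (!is.finite(alpha_l)) stop_invalid("alpha_l must be finite")
  if (length(D_l) != length(y) || length(y) != length(preds)) {
    stop_invalid("length mismatch")
  }
  un <- D_l * exp(-alpha_l * y * preds)
  Z <- sum(un)
  if (Z <= 0 || !is.finite(Z)) {
    stop("sample weights degenerated to zero or non-finite mass")
  }
  structure(list(D = un / Z, Z = Z), class = "boost_state")
}

#' Fit an attention-empowered ensemble of NLPNNs
#'
#' Boosting with exponential loss over NLPNN base learners. Round l fits an
#' NLPNN with the current sample weights entering the hinge loss (not by
#' resampling), measures its weighted error `epsilon_l` on the weighted
#' training sample, converts it to a vote weight `alpha_l`, and reweights
#' the samples so the next learner concentrates on the misdiagnosed cases.
#' Early stops: a perfect round (`epsilon = 0`) is kept with a capped alpha
#' and ends training; a round no better than chance (`epsilon >= 0.5`) is
#' discarded and ends training (an error if it happens on round 1).
#'
#' Per-round metrics (accuracy, recall, F1, G-mean) are recorded on a
#' held-out evaluation set: `val_table` when supplied, otherwise a
#' stratified 20% carve-out of `table` (the members then train on the
#' remaining 80%). [select_iterations()] consumes this history.
#'
#' @param table a [labeled_table()] of training data.
#' @param L_max maximum number of boosting rounds (default 10).
#' @param config an [nlpnn_config()]; round l uses seed `config$seed + l`.
#' @param val_table optional [labeled_table()] for the per-round metrics.
#' @return An `aepnn_model`: `members` (list of `nlpnn_model`), `alpha`,
#'   `epsilon`, `history` (data.frame with attribute `n_pos`), `L`.
#' @export
aepnn <- function(table, L_max = 10L, config = nlpnn_config(), val_table = NULL) {
  stopifnot(inherits(table, "labeled_table"))
  if (L_max < 1L) stop_invalid("L_max must be >= 1")
  table <- zero_fill(table)
  if (is.null(val_table)) {
    split <- with_seed(config$seed, stratified_holdout(table$y, 0.2))
    val_table <- labeled_table(table$X[split$val, , drop = FALSE],
                               table$y[split$val])
    table <- labeled_table(table$X[split$train, , drop = FALSE],
                           table$y[split$train])
  } else {
    val_table <- zero_fill(val_table)
  }
  n <- nrow(table$X)
  D <- rep(1 / n, n)
  members <- list()
  alphas <- numeric(0)
  epsilons <- numeric(0)
  history <- data.frame(round = integer(0), accuracy = numeric(0),
                        recall = numeric(0), f1 = numeric(0),
                        g_mean = numeric(0))
  val_scores <- numeric(nrow(val_table$X))
  for (l in seq_len(L_max)) {
    cfg_l <- config
    cfg_l$seed <- config$seed + (l - 1L)
    tab_l <- table
    tab_l$weights <- D
    h_l <- nlpnn(tab_l, cfg_l)
    preds <- predict(h_l, table$X)
    eps <- weighted_error(D, table$y, preds)
    if (eps >= 0.5) {
      if (l == 1L) {
        stop("base NLPNN is no better than chance on the weighted sample (epsilon >= 0.5)")
      }
      break
    }
    eps0 <- 1 / (2 * n)
    alpha <- if (eps == 0) classifier_weight(eps0) else classifier_weight(eps)
    members[[l]] <- h_l
    alphas <- c(alphas, alpha)
    epsilons <- c(epsilons, eps)
    val_scores <- val_scores + alpha * predict(h_l, val_table$X)
    cm <- confusion(val_table$y, sign_pos(val_scores))
    rep_l <- metric_report(cm)
    history <- rbind(history, data.frame(
      round = l, accuracy = rep_l$accuracy, recall = rep_l$recall,
      f1 = rep_l$f1, g_mean = rep_l$g_mean
    ))
    if (eps == 0) break
    D <- update_weights(D, alpha, table$y, preds)$D
  }
  attr(history, "n_pos") <- sum(val_table$y == 1)
  structure(
    list(members = members, alpha = alphas, epsilon = epsilons,
         L = length(members), history = history),
    class = "aepnn_model"
  )
}

#' @export
print.aepnn_model <- function(x, ...) {
  cat(sprintf("aepnn_model: %d NLPNN members, alpha in [%.3f, %.3f]\n",
              x$L, min(x$alpha), max(x$alpha)))
  invisible(x)
}

#' Ensemble decision scores
#'
#' @param model an `aepnn_model`.
#' @param X_new feature matrix.
#' @param L optional truncation: use only the first L members (e.g. the
#'   round chosen by [select_iterations()]).
#' @return `sum_l alpha_l * h_l(x)` per row.
#' @export
aepnn_score <- function(model, X_new, L = NULL) {
  stopifnot(inherits(model, "aepnn_model"))
  L <- L %||% model$L
  if (L < 1L || L > model$L) stop_invalid("L out of range")
  X_new <- as.matrix(X_new)
  if (nrow(X_new) == 0L) return(numeric(0))
  s <- numeric(nrow(X_new))
  for (l in seq_len(L)) {
    s <- s + model$alpha[l] * predict(model$members[[l]], X_new)
  }
  s
}

#' Predict labels with a boosted ensemble
#'
#' @param object an `aepnn_model`.
#' @param X_new feature matrix.
#' @param L optional member truncation.
#' @param ... unused.
#' @return Labels in \{-1, +1\}: `sign(sum_l alpha_l h_l(x))`, `sign(0) = +1`.
#' @export
predict.aepnn_model <- function(object, X_new, L = NULL, ...) {
  sign_pos(aepnn_score(object, X_new, L = L))
}

#' Pick the boosting round trading recall growth against accuracy drop
#'
#' Returns the round l maximizing
#' `(recall_l - recall_1)/recall_1 - (accuracy_1 - accuracy_l)/accuracy_1`,
#' growth rates taken relative to the single-classifier round; ties go to
#' the smallest l. When `recall_1 = 0` the growth denominator is floored at
#' `1 / (2 * n_pos)` so the rate stays finite (a recall climbing from zero
#' then shows as a very large growth rate).
#'
#' @param history data.frame with columns `accuracy` and `recall`, one row
#'   per round (as produced by [aepnn()]), with attribute `n_pos` or an
#'   explicit `n_pos` argument.
#' @param n_pos number of positive validation samples (for the zero-recall
#'   floor).
#' @return The selected round index (integer).
#' @export
select_iterations <- function(history, n_pos = attr(history, "n_pos")) {
  if (is.null(history) || nrow(history) < 1L) stop_invalid("history is empty")
  acc <- history$accuracy
  rec <- history$recall
  if (!is.finite(acc[1]) || acc[1] <= 0 || !is.finite(rec[1])) {
    stop_invalid("round-1 accuracy must be positive and recall defined")
  }
  rec1 <- rec[1]
  if (rec1 == 0) {
    if (is.null(n_pos) || n_pos < 1) stop_invalid("n_pos needed when recall_1 = 0")
    rec1 <- 1 / (2 * n_pos)
  }
  obj <- (rec - rec[1]) / rec1 - (acc[1] - acc) / acc[1]
  which.max(obj)
}
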