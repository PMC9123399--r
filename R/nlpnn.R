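#' Fit a network-limited polynomial neural network
#'
#' End-to-end estimator: builds the depth/width-capped polynomial feature
#' stack ([build_stack()]), then trains the per-layer hinge-loss readouts
#' and keeps the (layer, lambda) pair with the best validation accuracy
#' ([select_best()]). Missing feature entries are zero-filled. Sample
#' weights on the table, when present, weight the readout loss — this is
#' the hook the boosting wrapper uses.
#'
#' If the labels are single-class the fit degenerates gracefully: a
#' constant classifier predicting that class everywhere is returned (the
#' hinge problem has no second class to trade off against).
#'
#' @param table a [labeled_table()].
#' @param config an [nlpnn_config()]; `omega = NULL` resolves to two layers
#'   of width d+1.
#' @return An object of class `nlpnn_model`: fields `stack`, `readout`,
#'   `config`, `label_map`.
#' @examples
#' syn <- synth_generate(synth_spec(n = 120, d = 2, degree = 1, seed = 3))
#' fit <- nlpnn(syn$table, nlpnn_config(seed = 3))
#' table(predict(fit, syn$table$X), syn$table$y)
#' @export
nlpnn <- function(table, config = nlpnn_config()) {
  stopifnot(inherits(table, "labeled_table"), inherits(config, "nlpnn_config"))
  table <- zero_fill(table)
  config <- resolve_omega(config, ncol(table$X))
  with_seed(config$seed, {
    if (length(unique(table$y)) == 1L) {
      stack <- new_feature_stack(list(build_first_layer(table, config)),
                                 nrow(table$X))
      readout <- structure(
        list(nu = c(table$y[1], rep(0, ncol(stack$layers[[1]]$F))),
             lambda_ = config$lambda_grid[1], m = 1L,
             train_objective = 0),
        class = "readout_model"
      )
    } else {
      stack <- build_stack(table, config)
      readout <- select_best(stack, table$y, config$lambda_grid,
                             weights = table$weights, config = config)
    }
    structure(
      list(stack = stack, readout = readout, config = config,
           label_map = c(negative = -1, positive = 1)),
      class = "nlpnn_model"
    )
  })
}

#' @export
print.nlpnn_model <- function(x, ...) {
  widths <- vapply(x$stack$layers, function(l) {
    if (!is.null(l$F)) ncol(l$F)
    else if (l$level == 1L) ncol(l$construction)
    else length(l$construction)
  }, integer(1))
  cat(sprintf(
    "nlpnn_model: %d layers (widths %s); readout uses layers 1..%d, lambda = %g\n",
    length(widths), paste(widths, collapse = ","), x$readout$m, x$readout$lambda_
  ))
  invisible(x)
}

#' Decision scores of a fitted NLPNN
#'
#' @param model an `nlpnn_model`.
#' @param X_new numeric matrix with the training number of feature columns.
#' @return Real-valued scores; the predicted label is `sign(score)` with
#'   `sign(0) = +1`.
#' @export
nlpnn_score <- function(model, X_new) {
  stopifnot(inherits(model, "nlpnn_model"))
  X_new <- as.matrix(X_new)
  if (nrow(X_new) == 0L) return(numeric(0))
  feats <- transform_stack(model$stack, X_new, m = model$readout$m)
  decision_score(model$readout, feats)
}

#' Predict labels with a fitted NLPNN
#'
#' @param object an `nlpnn_model`.
#' @param X_new feature matrix (NA entries zero-filled).
#' @param ... unused.
#' @return Labels in \{-1, +1\}.
#' @export
predict.nlpnn_model <- function(object, X_new, ...) {
  sign_pos(nlpnn_score(object, X_new))
}
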