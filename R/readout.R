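#' Hinge-loss objective of a linear readout
#'
#' The per-layer readout minimizes the weighted hinge loss plus an L2-norm
#' penalty on the coefficients (the intercept is not penalized):
#' `sum_i w_i * max(0, 1 - y_i * (b + f_i . nu)) + lambda * ||nu||_2`,
#' with `w_i = 1/n` when no sample weights are supplied.
#'
#' @param par numeric vector `c(intercept, nu)`.
#' @param features n x p feature matrix.
#' @param y labels in \{-1, +1\}.
#' @param lambda_ positive regularization factor.
#' @param weights optional distribution over samples.
#' @return The objective value (a scalar).
#' @export
readout_objective <- function(par, features, y, lambda_, weights = NULL) {
  w <- weights %||% rep(1 / length(y), length(y))
  s <- par[1] + drop(features %*% par[-1])
  sum(w * pmax(0, 1 - s * y)) + lambda_ * sqrt(sum(par[-1]^2))
}

#' Fit a hinge-loss linear readout by stochastic gradient descent
#'
#' Minimizes [readout_objective()] by seeded mini-batch subgradient descent
#' with a staged geometric step schedule: the run is divided into `stages`
#' stages, stage s uses the constant step `eta0 * 2^-(s-1)`, the iterates of
#' each stage are averaged (Polyak-Ruppert), each stage average is rescaled
#' by an exact 1-D line search over its scalar multiple, and the candidate
#' with the lowest full-data objective is returned. Early large steps let
#' the iterate travel to weakly regularized optima (whose norm can be large
#' on separable data); late small steps plus averaging polish the solution,
#' and the scale search removes norm overshoot.
#' At least `min_updates` mini-batch updates are performed regardless of
#' `epochs`, so small-n problems are not under-optimized.
#'
#' With `weights` supplied, each sample's hinge term is scaled by its
#' weight — this is how the boosting wrapper redirects attention to
#' misdiagnosed cases.
#'
#' @param features n x p numeric feature matrix (finite entries).
#' @param y labels in \{-1, +1\}.
#' @param lambda_ positive regularization factor.
#' @param weights optional non-negative distribution over samples.
#' @param epochs,batch_size,eta0 SGD settings (see [nlpnn_config()]);
#'   `eta0 = NULL` scales the initial step with the regularization factor,
#'   `max(0.5, 0.01 / lambda_)`, since weakly regularized optima can have
#'   large norm and the iterate must travel correspondingly far.
#' @param stages number of geometric step-decay stages.
#' @param min_updates lower bound on total mini-batch updates.
#' @param seed optional integer; when given, the SGD shuffling is run under
#'   this seed without disturbing the caller's RNG.
#' @return A `readout_model`: list with `nu` (length p+1, intercept first),
#'   `lambda_`, `m` (layer cutoff, filled by [select_best()]),
#'   `train_objective`.
#' @export
fit_readout <- function(features, y, lambda_, weights = NULL,
                        epochs = 160L, batch_size = 16L, eta0 = NULL,
                        stages = 16L, min_updates = 48000L, seed = NULL) {
  features <- as.matrix(features)
  n <- nrow(features)
  if (length(y) != n) stop_invalid("features rows must match length(y)")
  if (!all(is.finite(features))) stop_invalid("features must be finite")
  if (lambda_ <= 0) stop_invalid("lambda_ must be positive")
  eta0 <- eta0 %||% max(0.5, 0.01 / lambda_)
  w <- weights %||% rep(1 / n, n)
  if (any(w < 0) || abs(sum(w) - 1) > 1e-9) {
    stop_invalid("weights must be a distribution over samples")
  }
  run <- function() {
    p <- ncol(features)
    par <- numeric(p + 1)
    best <- par
    best_obj <- readout_objective(par, features, y, lambda_, w)
    bs <- min(batch_size, n)
    nb <- ceiling(n / bs)
    total_ep <- max(epochs, ceiling(min_updates / nb))
    ep_per <- max(1L, total_ep %/% stages)
    for (s in seq_len(stages)) {
      eta <- eta0 * 2^(-(s - 1))
      avg <- numeric(p + 1)
      navg <- 0L
      for (ep in seq_len(ep_per)) {
        idx <- sample.int(n)
        for (b in seq_len(nb)) {
          rows <- idx[((b - 1L) * bs + 1L):min(b * bs, n)]
          Fb <- features[rows, , drop = FALSE]
          yb <- y[rows]
          sc <- par[1] + drop(Fb %*% par[-1])
          active <- (1 - sc * yb) > 0
          g <- numeric(p + 1)
          if (any(active)) {
            cw <- (n / length(rows)) * w[rows][active] * yb[active]
            g[1] <- -sum(cw)
            g[-1] <- -drop(crossprod(Fb[active, , drop = FALSE], cw))
          }
          nn <- sqrt(sum(par[-1]^2))
          if (nn > 0) g[-1] <- g[-1] + lambda_ * par[-1] / nn
          par <- par - eta * g
          avg <- avg + par
          navg <- navg + 1L
        }
      }
      cand <- avg / navg
      # exact line search over the scale of the averaged iterate: the
      # objective is convex in a scalar multiple, and norm overshoot is the
      # dominant error on weakly regularized (near-separable) problems
      cc <- stats::optimize(
        function(cc) readout_objective(cc * cand, features, y, lambda_, w),
        c(0, 4), tol = 1e-10
      )$minimum
      cand <- cc * cand
      cand_obj <- readout_objective(cand, features, y, lambda_, w)
      if (cand_obj < best_obj) {
        best_obj <- cand_obj
        best <- cand
      }
    }
    best
  }
  par <- if (is.null(seed)) run() else with_seed(seed, run())
  structure(
    list(nu = par, lambda_ = lambda_, m = NA_integer_,
         train_objective = readout_objective(par, features, y, lambda_, w)),
    class = "readout_model"
  )
}

#' Fit the hinge readout with a deterministic smoothed-Newton solver
#'
#' High-accuracy minimizer of [readout_objective()] for small instances:
#' the hinge and the norm penalty are smoothed (Huber-style, smoothing
#' parameter driven down by continuation 1e-2 -> 1e-8) and each stage is
#' solved by BFGS with analytic gradients. The smoothing gap is bounded by
#' `delta * (1/2 + lambda)`, negligible at the final stage. Intended as an
#' exact reference for the SGD fit and for small-sample analyses.
#'
#' @inheritParams fit_readout
#' @return A `readout_model`.
#' @export
fit_readout_exact <- function(features, y, lambda_, weights = NULL) {
  features <- as.matrix(features)
  n <- nrow(features)
  w <- weights %||% rep(1 / n, n)
  p <- ncol(features)
  smooth_obj <- function(par, delta) {
    s <- par[1] + drop(features %*% par[-1])
    z <- 1 - s * y
    h <- ifelse(z <= 0, 0, ifelse(z < delta, z^2 / (2 * delta), z - delta / 2))
    sum(w * h) + lambda_ * (sqrt(sum(par[-1]^2) + delta^2) - delta)
  }
  smooth_grad <- function(par, delta) {
    s <- par[1] + drop(features %*% par[-1])
    z <- 1 - s * y
    hd <- ifelse(z <= 0, 0, ifelse(z < delta, z / delta, 1))
    cw <- -w * hd * y
    g <- c(sum(cw), drop(crossprod(features, cw)))
    g[-1] <- g[-1] + lambda_ * par[-1] / sqrt(sum(par[-1]^2) + delta^2)
    g
  }
  par <- numeric(p + 1)
  for (delta in 10^c(-2, -4, -6, -8)) {
    opt <- stats::optim(par, fn = smooth_obj, gr = smooth_grad, delta = delta,
                        method = "BFGS",
                        control = list(maxit = 1000, reltol = 1e-14))
    par <- opt$par
  }
  structure(
    list(nu = par, lambda_ = lambda_, m = NA_integer_,
         train_objective = readout_objective(par, features, y, lambda_, w)),
    class = "readout_model"
  )
}

#' Decision scores of a readout
#'
#' @param model a `readout_model`.
#' @param features matrix whose width matches `length(model$nu) - 1`.
#' @return `intercept + features %*% nu`; predictions are
#'   `sign(score)` with `sign(0) = +1`.
#' @export
decision_score <- function(model, features) {
  features <- as.matrix(features)
  if (ncol(features) != length(model$nu) - 1L) {
    stop_invalid("feature width ", ncol(features), " does not match readout (",
                 length(model$nu) - 1L, ")")
  }
  model$nu[1] + drop(features %*% model$nu[-1])
}

# Stratified index split: returns list(train =, val =). Guarantees at least
# one training sample per class; uses the current RNG stream.
stratified_holdout <- function(y, fraction) {
  val <- integer(0)
  for (cls in unique(y)) {
    idx <- which(y == cls)
    k <- min(round(length(idx) * fraction), length(idx) - 1L)
    if (k > 0) val <- c(val, sample(idx, k))
  }
  list(train = setdiff(seq_along(y), val), val = sort(val))
}

#' Select the best (layer, lambda) readout on a validation split
#'
#' For every layer cutoff m and every lambda in the grid, fits a readout on
#' a stratified training portion using the features of layers 1..m and
#' scores 0-1 accuracy on the held-out validation portion (weighted
#' accuracy when sample weights are supplied). The winner — ties resolved
#' toward smaller m, then larger lambda — is refit on the full training
#' data and returned.
#'
#' @param stack a `feature_stack` built on the training data.
#' @param y training labels.
#' @param lambda_grid positive reals.
#' @param weights optional distribution over samples.
#' @param config an [nlpnn_config()] providing SGD settings and the
#'   validation fraction.
#' @return A `readout_model` with `m` set to the chosen layer cutoff.
#' @export
select_best <- function(stack, y, lambda_grid, weights = NULL, config = nlpnn_config()) {
  if (length(lambda_grid) == 0) stop_invalid("lambda_grid is empty")
  split <- stratified_holdout(y, config$validation_fraction)
  w <- weights %||% rep(1 / length(y), length(y))
  M <- length(stack$layers)
  best <- NULL
  best_acc <- -Inf
  for (m in seq_len(M)) {
    feats <- stack_features(stack, m)
    f_tr <- feats[split$train, , drop = FALSE]
    f_va <- feats[split$val, , drop = FALSE]
    w_tr <- w[split$train] / sum(w[split$train])
    w_va <- if (sum(w[split$val]) > 0) {
      w[split$val] / sum(w[split$val])
    } else {
      rep(1 / length(split$val), length(split$val))
    }
    for (lambda_ in sort(lambda_grid, decreasing = TRUE)) {
      fit <- fit_readout(f_tr, y[split$train], lambda_, weights = w_tr,
                         epochs = config$epochs, batch_size = config$batch_size,
                         eta0 = config$eta0)
      pred <- sign_pos(decision_score(fit, f_va))
      acc <- sum(w_va * (pred == y[split$val]))
      if (acc > best_acc) {
        best_acc <- acc
        best <- list(m = m, lambda_ = lambda_)
      }
    }
  }
  feats <- stack_features(stack, best$m)
  final <- fit_readout(feats, y, best$lambda_, weights = weights,
                       epochs = config$epochs, batch_size = config$batch_size,
                       eta0 = config$eta0)
  final$m <- best$m
  final
}
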