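#' Synthetic dataset specification
#'
#' Describes a dataset with the structure the polynomial-network estimators
#' assume: Gaussian features, labels given by the sign of a hidden
#' polynomial thresholded to hit a target class-imbalance ratio, optional
#' label noise and missingness. Mirrors the shapes of the chronic-disease
#' benchmarks (positive:negative ratios from roughly 1:0.24 to 1:12.78).
#'
#' @param n number of samples (>= 10).
#' @param d number of features.
#' @param degree total degree of the hidden polynomial (M_true).
#' @param imbalance_ratio positive real r: target positive:negative = 1:r
#'   (so the positive fraction is 1/(1+r)).
#' @param label_noise independent flip probability in `[0, 0.5)`.
#' @param missing_rate fraction of feature cells masked as missing, in
#'   `[0, 1)`.
#' @param seed integer seed; generation is fully reproducible from it.
#' @return A `synth_spec`.
#' @export
synth_spec <- function(n, d, degree = 2L, imbalance_ratio = 1,
                       label_noise = 0, missing_rate = 0, seed = 1L) {
  if (n < 10) stop_invalid("n must be >= 10")
  if (d < 1) stop_invalid("d must be >= 1")
  if (degree < 1) stop_invalid("degree must be >= 1")
  if (imbalance_ratio <= 0) stop_invalid("imbalance_ratio must be positive")
  if (label_noise < 0 || label_noise >= 0.5) {
    stop_invalid("label_noise must be in [0, 0.5)")
  }
  if (missing_rate < 0 || missing_rate >= 1) {
    stop_invalid("missing_rate must be in [0, 1)")
  }
  structure(
    list(n = as.integer(n), d = as.integer(d), degree = as.integer(degree),
         imbalance_ratio = imbalance_ratio, label_noise = label_noise,
         missing_rate = missing_rate, seed = as.integer(seed)),
    class = "synth_spec"
  )
}

# Evaluate the ground-truth polynomial on rows of X.
eval_truth_poly <- function(truth, X) {
  drop(monomial_design(as.matrix(X), truth$exponents) %*% truth$coefficients)
}

#' Generate a synthetic labeled dataset
#'
#' Draws `n x d` i.i.d. standard-normal features and a hidden polynomial
#' with standard-normal coefficients over all monomials of total degree at
#' most `degree`. The decision threshold tau is calibrated by bisection on
#' a large probe sample (20000 draws) so the realized positive fraction is
#' within 10% relative of `1/(1 + r)`; labels are `sign(p(x) - tau)` with
#' `sign(0) = +1`, then flipped independently with probability
#' `label_noise`, and feature cells are masked (`NA`) at `missing_rate`.
#'
#' @param spec a [synth_spec()].
#' @return List with `table` (a [labeled_table()], possibly containing `NA`
#'   cells) and `truth` (exponents, coefficients, tau, degree) for
#'   oracle checks via [bayes_labels()].
#' @export
synth_generate <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  with_seed(spec$seed, {
    exponents <- monomial_exponents(spec$d, spec$degree)
    coefficients <- stats::rnorm(nrow(exponents))
    truth <- list(exponents = exponents, coefficients = coefficients,
                  tau = 0, degree = spec$degree)
    target <- 1 / (1 + spec$imbalance_ratio)
    probe <- matrix(stats::rnorm(20000 * spec$d), ncol = spec$d)
    pv <- eval_truth_poly(truth, probe)
    lo <- min(pv); hi <- max(pv)
    tau <- 0
    for (step in seq_len(60)) {
      tau <- (lo + hi) / 2
      frac <- mean(pv > tau)
      if (frac > target) lo <- tau else hi <- tau
    }
    if (abs(mean(pv > tau) - target) > 0.1 * target) {
      stop("imbalance calibration failed: polynomial too degenerate for ratio 1:",
           spec$imbalance_ratio)
    }
    truth$tau <- tau
    X <- matrix(stats::rnorm(spec$n * spec$d), ncol = spec$d)
    y <- bayes_labels(truth, X)
    if (spec$label_noise > 0) {
      flip <- stats::runif(spec$n) < spec$label_noise
      y[flip] <- -y[flip]
    }
    if (spec$missing_rate > 0) {
      mask <- matrix(stats::runif(spec$n * spec$d) < spec$missing_rate,
                     ncol = spec$d)
      X[mask] <- NA_real_
    }
    list(table = labeled_table(X, y), truth = truth)
  })
}

#' Noise-free oracle labels of a synthetic ground truth
#'
#' @param truth the `truth` record returned by [synth_generate()].
#' @param X feature matrix with `truth`'s number of variables.
#' @return Labels `sign(p(x) - tau)` in \{-1, +1\} (`sign(0) = +1`).
#' @export
bayes_labels <- function(truth, X) {
  sign_pos(eval_truth_poly(truth, X) - truth$tau)
}
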