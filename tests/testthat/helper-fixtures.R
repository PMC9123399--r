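# Shared fixtures, all built in code.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Affine ground truth with a guaranteed margin: labels sign(w.x + b) with
# samples closer than `margin` to the boundary resampled away.
make_affine_table <- function(n = 150, d = 2, margin = 0.4, seed = 1) {
  set.seed(seed)
  w <- c(1, -2, rep(1, max(0, d - 2)))[seq_len(d)]
  X <- matrix(0, 0, d)
  while (nrow(X) < n) {
    cand <- matrix(rnorm(2 * n * d), ncol = d)
    keep <- abs(cand %*% w + 0.3) > margin
    X <- rbind(X, cand[keep, , drop = FALSE])
  }
  X <- X[seq_len(n), , drop = FALSE]
  y <- as.numeric(sign(X %*% w + 0.3))
  labeled_table(X, y)
}

# Balanced XOR-style grid: labels sign(x1 * x2), grid values bounded away
# from the axes so a margin exists; no affine rule exceeds 0.75 here.
make_xor_grid <- function(step = 0.25) {
  g <- seq(step, 1, by = step)
  g <- c(-rev(g), g)
  X <- as.matrix(expand.grid(x1 = g, x2 = g))
  dimnames(X) <- NULL
  labeled_table(X, as.numeric(sign(X[, 1] * X[, 2])))
}

# Fresh evaluation set labeled by a synthetic ground truth.
make_oracle_testset <- function(truth, d, n = 1000, seed = 99) {
  set.seed(seed)
  X <- matrix(rnorm(n * d), ncol = d)
  labeled_table(X, bayes_labels(truth, X))
}

# Small random hinge instances with informative noisy labels, for comparing
# the SGD readout against the smoothed-Newton reference solver.
make_readout_instance <- function(n, p, flip = 0.1) {
  feats <- matrix(rnorm(n * p), n, p)
  b <- rnorm(p)
  y <- ifelse(feats %*% b + 0.5 * rnorm(n) >= 0, 1, -1)
  sw <- runif(n) < flip
  y[sw] <- -y[sw]
  list(features = feats, y = as.numeric(y))
}

# Decision stump: best weighted threshold on a single feature.
fit_stump <- function(x, y, w) {
  cuts <- sort(unique(x))
  cuts <- c(cuts[1] - 1, (cuts[-1] + cuts[-length(cuts)]) / 2)
  best <- NULL
  best_err <- Inf
  for (cut in cuts) for (dir in c(1, -1)) {
    pred <- ifelse(dir * (x - cut) >= 0, 1, -1)
    err <- sum(w * (pred != y))
    if (err < best_err) {
      best_err <- err
      best <- list(cut = cut, dir = dir, err = err, pred = pred)
    }
  }
  best
}
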