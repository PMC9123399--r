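#' Build the first polynomial feature layer
#'
#' The first non-output layer is a partial orthogonal basis of the augmented
#' data matrix `[1 X]`: its columns are the leading left singular vectors,
#' each rescaled to Euclidean norm sqrt(n). At most `omega[1]` columns are
#' kept, fewer when `[1 X]` is rank deficient (singular values below
#' `rank_tol * s_max` are treated as zero). The stored construction is the
#' right-singular projection, so the same linear map can be replayed on new
#' samples.
#'
#' @param table a [labeled_table].
#' @param config an [nlpnn_config].
#' @return A `basis_layer`: list with `level = 1`, `F` (n x w1 matrix) and
#'   `construction` (the (d+1) x w1 projection applied to `[1, x]` rows).
#' @export
build_first_layer <- function(table, config) {
  stopifnot(inherits(table, "labeled_table"), inherits(config, "nlpnn_config"))
  config <- resolve_omega(config, ncol(table$X))
  X <- table$X
  if (anyNA(X)) stop_invalid("feature matrix contains NA; zero_fill() first")
  n <- nrow(X)
  A <- cbind(1, X)
  sv <- canonicalize_svd_signs(svd(A))
  rank <- sum(sv$d > config$rank_tol * sv$d[1])
  w1 <- min(config$omega[1], rank)
  keep <- seq_len(w1)
  # [1 X] %*% (V_k / sigma_k) * sqrt(n) = sqrt(n) U_k, columns of norm sqrt(n)
  proj <- sweep(sv$v[, keep, drop = FALSE], 2, sv$d[keep], "/") * sqrt(n)
  F1 <- sv$u[, keep, drop = FALSE] * sqrt(n)
  new_basis_layer(level = 1L, F = F1, construction = proj)
}

new_basis_layer <- function(level, F, construction) {
  structure(list(level = as.integer(level), F = F, construction = construction),
            class = "basis_layer")
}

#' Candidate degree-m feature columns by Hadamard products
#'
#' Forms every elementwise product of a column of layer m-1 with a column of
#' layer 1, in i-major / j-minor order (i indexes the previous layer, j the
#' first layer). These candidates span, together with the lower layers, all
#' polynomial values of degree up to m on the training samples.
#'
#' @param prev the `basis_layer` at level m-1.
#' @param first the level-1 `basis_layer`.
#' @return An n x (w_{m-1} * w_1) matrix with attribute `pairs`, a
#'   data.frame of the (i, j) index pairs per column.
#' @export
candidate_products <- function(prev, first) {
  stopifnot(inherits(prev, "basis_layer"), inherits(first, "basis_layer"))
  if (nrow(prev$F) != nrow(first$F)) stop_invalid("layers built on different n")
  wp <- ncol(prev$F)
  w1 <- ncol(first$F)
  pairs <- data.frame(
    i = rep(seq_len(wp), each = w1),
    j = rep(seq_len(w1), times = wp)
  )
  out <- prev$F[, pairs$i, drop = FALSE] * first$F[, pairs$j, drop = FALSE]
  attr(out, "pairs") <- pairs
  out
}

# Orthonormal basis of the column span of M (columns with norm below tol
# after projection are dropped); modified Gram-Schmidt with reorthogonalization.
orthonormal_basis <- function(M, tol) {
  n <- nrow(M)
  Q <- matrix(0, n, 0)
  for (k in seq_len(ncol(M))) {
    v <- M[, k]
    for (pass in 1:2) if (ncol(Q) > 0) v <- v - Q %*% crossprod(Q, v)
    nv <- sqrt(sum(v^2))
    if (nv > tol) Q <- cbind(Q, v / nv)
  }
  Q
}

#' Greedy orthogonal least squares selection of layer columns
#'
#' Selects up to `width_cap` candidate columns by supervised orthogonal
#' least squares: at each step the candidate whose component orthogonal to
#' everything already in the stack (plus previously selected columns) has
#' the largest squared correlation with the labels wins; ties go to the
#' lowest candidate index. Selection works on orthogonalized copies, but the
#' stored column is the original candidate rescaled to norm sqrt(n), and the
#' construction records (i, j, scale) so the column can be replayed on new
#' samples. Candidates whose orthogonal residual has norm at most
#' `rank_tol * sqrt(n)` are numerically dependent and skipped; an empty
#' layer signals that construction should stop.
#'
#' @param candidates matrix from [candidate_products()] (with `pairs` attr).
#' @param accum a `feature_stack` of the layers built so far.
#' @param y label vector.
#' @param width_cap maximum number of columns to select.
#' @param rank_tol relative dependence tolerance.
#' @return A `basis_layer` at level `max(accum levels) + 1`; its `F` may
#'   have zero columns.
#' @export
select_layer_columns <- function(candidates, accum, y, width_cap, rank_tol) {
  stopifnot(inherits(accum, "feature_stack"))
  pairs <- attr(candidates, "pairs")
  if (is.null(pairs)) stop_invalid("candidates must come from candidate_products()")
  n <- nrow(candidates)
  if (length(y) != n) stop_invalid("y length mismatch")
  level <- max(vapply(accum$layers, `[[`, integer(1), "level")) + 1L
  tol <- rank_tol * sqrt(n)

  Q <- orthonormal_basis(stack_features(accum), tol)
  # residuals of all candidates against the current span, updated as we select
  R <- candidates
  for (pass in 1:2) R <- R - Q %*% crossprod(Q, R)

  sel <- integer(0)
  Fm <- matrix(0, n, 0)
  records <- list()
  while (length(sel) < width_cap) {
    rn2 <- colSums(R^2)
    ok <- rn2 > tol^2
    ok[sel] <- FALSE
    if (!any(ok)) break
    gain <- rep(-Inf, ncol(R))
    gain[ok] <- (crossprod(R[, ok, drop = FALSE], y))^2 / rn2[ok]
    best <- which.max(gain) # first max = lowest index on ties
    if (gain[best] == 0) break
    sel <- c(sel, best)
    orig <- candidates[, best]
    scale <- sqrt(n) / sqrt(sum(orig^2))
    Fm <- cbind(Fm, orig * scale)
    records[[length(records) + 1L]] <- list(
      i = pairs$i[best], j = pairs$j[best], scale = scale
    )
    # extend the orthonormal basis with the chosen residual direction
    q <- R[, best]
    q <- q - Q %*% crossprod(Q, q)
    q <- q / sqrt(sum(q^2))
    Q <- cbind(Q, q)
    R <- R - q %*% crossprod(q, R)
  }
  new_basis_layer(level = level, F = Fm, construction = records)
}

new_feature_stack <- function(layers, n) {
  structure(list(layers = layers, n = as.integer(n)), class = "feature_stack")
}

# All stored feature columns of layers 1..m (default: all layers).
stack_features <- function(stack, m = NULL) {
  layers <- stack$layers
  if (!is.null(m)) layers <- layers[seq_len(m)]
  do.call(cbind, lapply(layers, `[[`, "F"))
}

#' @export
print.feature_stack <- function(x, ...) {
  widths <- vapply(x$layers, function(l) ncol(l$F), integer(1))
  cat(sprintf("feature_stack: %d layers on n = %d (widths: %s)\n",
              length(x$layers), x$n, paste(widths, collapse = ", ")))
  invisible(x)
}

#' Build the full polynomial feature stack
#'
#' Runs [build_first_layer()], then alternates [candidate_products()] and
#' [select_layer_columns()] for layers 2..M (M = `length(omega)`).
#' Construction stops early at the first empty layer (no candidate adds
#' numerical rank). Deterministic given the table and config.
#'
#' @inheritParams build_first_layer
#' @return A `feature_stack`.
#' @export
build_stack <- function(table, config) {
  config <- resolve_omega(config, ncol(table$X))
  first <- build_first_layer(table, config)
  layers <- list(first)
  stack <- new_feature_stack(layers, nrow(table$X))
  M <- length(config$omega)
  if (M >= 2) {
    for (m in 2:M) {
      cand <- candidate_products(layers[[m - 1L]], first)
      layer <- select_layer_columns(cand, stack, table$y,
                                    width_cap = config$omega[m],
                                    rank_tol = config$rank_tol)
      if (ncol(layer$F) == 0L) break
      layers[[m]] <- layer
      stack <- new_feature_stack(layers, nrow(table$X))
    }
  }
  stack
}

#' Replay a feature stack on new samples
#'
#' Layer 1 applies the stored affine projection to augmented rows `[1, x]`;
#' each deeper column is `scale * (column i of the previous transformed
#' layer) * (column j of the transformed first layer)`, exactly as recorded
#' at training time. On the training matrix this reproduces the stored
#' features.
#'
#' @param stack a `feature_stack`.
#' @param X_new numeric matrix with the training number of columns; `NA`
#'   entries are zero-filled.
#' @param m optional layer cutoff: return features of layers 1..m only.
#' @return Numeric matrix with one row per row of `X_new`.
#' @export
transform_stack <- function(stack, X_new, m = NULL) {
  stopifnot(inherits(stack, "feature_stack"))
  X_new <- as.matrix(X_new)
  storage.mode(X_new) <- "double"
  X_new[is.na(X_new)] <- 0
  d_expected <- nrow(stack$layers[[1]]$construction) - 1L
  if (ncol(X_new) != d_expected) {
    stop_invalid("X_new has ", ncol(X_new), " columns; stack expects ", d_expected)
  }
  m <- m %||% length(stack$layers)
  first <- cbind(1, X_new) %*% stack$layers[[1]]$construction
  out <- list(first)
  prev <- first
  if (m >= 2) {
    for (lev in 2:m) {
      recs <- stack$layers[[lev]]$construction
      cols <- vapply(recs, function(r) r$scale * prev[, r$i] * first[, r$j],
                     numeric(nrow(X_new)))
      cur <- matrix(cols, nrow = nrow(X_new))
      out[[lev]] <- cur
      prev <- cur
    }
  }
  do.call(cbind, out)
}

#' Exponent matrix of all monomials up to a total degree
#'
#' Enumerates every d-vector of non-negative integer exponents with total
#' degree at most `degree`; there are choose(d + degree, degree) of them.
#' Used by the synthetic generator (ground-truth polynomials) and by tests
#' that compare the learned stack against the full monomial design matrix.
#'
#' @param d number of variables.
#' @param degree maximum total degree.
#' @return Integer matrix, one row per monomial, d columns.
#' @export
monomial_exponents <- function(d, degree) {
  # enumerate exponent vectors with total degree <= degree, one variable at
  # a time (choose(d + degree, degree) rows; never materializes a full grid)
  rec <- function(vars_left, deg_left) {
    if (vars_left == 0L) return(matrix(0L, 1, 0))
    blocks <- lapply(0:deg_left, function(a) {
      cbind(a, rec(vars_left - 1L, deg_left - a))
    })
    do.call(rbind, blocks)
  }
  grid <- rec(d, as.integer(degree))
  grid <- grid[order(rowSums(grid)), , drop = FALSE]
  dimnames(grid) <- NULL
  grid
}

#' Evaluate the monomial design matrix
#'
#' @param X numeric matrix (n x d).
#' @param exponents matrix from [monomial_exponents()].
#' @return n x nrow(exponents) matrix whose columns are the monomials
#'   evaluated on the rows of `X`.
#' @export
monomial_design <- function(X, exponents) {
  X <- as.matrix(X)
  apply(exponents, 1, function(a) {
    apply(sweep(X, 2, a, `^`), 1, prod)
  })
}
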