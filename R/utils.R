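#' @keywords internal
"_PACKAGE"

# Run code with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  if (!is.null(seed)) set.seed(as.integer(seed))
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_invalid <- function(...) {
  stop(structure(
    class = c("nlpnn_invalid_input", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

# sign with the fixed tie convention sign(0) = +1
sign_pos <- function(x) {
  out <- rep(1, length(x))
  out[x < 0] <- -1
  out
}

# Deterministic sign canonicalization for SVD factors: flip each column of V
# (and the matching column of U) so its largest-magnitude entry is positive.
canonicalize_svd_signs <- function(sv) {
  flips <- apply(sv$v, 2, function(col) {
    k <- which.max(abs(col))
    if (col[k] < 0) -1 else 1
  })
  sv$u <- sweep(sv$u, 2, flips, "*")
  sv$v <- sweep(sv$v, 2, flips, "*")
  sv
}
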