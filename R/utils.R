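#' @importFrom Rcpp sourceCpp
#' @importFrom stats approx quantile rnorm runif sd setNames pnorm
#' @importFrom rlang .data
#' @useDynLib synthmv, .registration = TRUE
NULL

# Run code under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Deterministic per-stage seed derivation; keeps results within 32-bit range.
derive_seed <- function(seed, offset) {
  (as.integer(seed) + 97L * as.integer(offset)) %% 2147483587L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_synthmv <- function(...) stop(sprintf(...), call. = FALSE)
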