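#' Run code with a temporarily fixed RNG seed
#'
#' Sets the RNG seed for the duration of `code` and restores the caller's
#' RNG state afterwards, so seeded helpers do not perturb the global
#' random stream.
#'
#' @param seed Integer seed, or `NULL` to leave the RNG untouched.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  code
}

#' Derive a reproducible child seed
#'
#' Expands one master seed into a stream of per-component seeds by a fixed
#' affine map modulo the largest 32-bit prime, so every subsystem is
#' independently reproducible from a single seed.
#'
#' @param seed Master integer seed.
#' @param k Child index (any non-negative integer).
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
child_seed <- function(seed, k) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.numeric(k))
  m <- 2147483647          # 2^31 - 1, prime
  s <- (abs(as.numeric(seed)) %% m)
  as.integer(((s * 48271) %% m + (as.numeric(k) * 16807) %% m) %% m + 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
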