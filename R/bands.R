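#' Define a frequency band
#'
#' @param name Band name (e.g. `"alpha"`).
#' @param low,high Band edges in Hz; `0 < low < high`.
#' @return An object of class `frequency_band`.
#' @examples
#' frequency_band("alpha", 8, 13)
#' @export
frequency_band <- function(name, low, high) {
  stopifnot(is.character(name), length(name) == 1)
  low <- as.numeric(low); high <- as.numeric(high)
  if (!(is.finite(low) && is.finite(high) && low > 0 && high > low)) {
    stop("frequency_band: need 0 < low < high, got [", low, ", ", high, "]")
  }
  structure(list(name = name, low = low, high = high),
            class = "frequency_band")
}

#' The five canonical neural oscillation bands
#'
#' delta (1-4 Hz), theta (4-8 Hz), alpha (8-13 Hz), beta (13-30 Hz) and
#' gamma (30-48 Hz), the standard partition used when computing
#' band-specific electrophysiological connectivity.
#'
#' @return A named list of [frequency_band] objects.
#' @export
canonical_bands <- function() {
  list(
    delta = frequency_band("delta", 1, 4),
    theta = frequency_band("theta", 4, 8),
    alpha = frequency_band("alpha", 8, 13),
    beta  = frequency_band("beta", 13, 30),
    gamma = frequency_band("gamma", 30, 48)
  )
}

#' @export
print.frequency_band <- function(x, ...) {
  cat(sprintf("<frequency_band> %s: %g-%g Hz\n", x$name, x$low, x$high))
  invisible(x)
}
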