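#' Construct a regional time-series object
#'
#' Holds one representative signal per brain region, sampled at a common
#' rate.  Used both for electrophysiological (MEG-like) and haemodynamic
#' (fMRI-like) channels.
#'
#' @param data regions x samples numeric matrix.
#' @param sampling_rate Sampling rate in Hz.
#' @param region_labels Character vector, one per region; defaults to the
#'   rownames or `R1..RP`.
#' @param band Optional [frequency_band] the data are limited to.
#' @param modality `"electrophysiological"` or `"haemodynamic"`.
#' @return An object of class `regional_ts`.
#' @export
regional_ts <- function(data, sampling_rate, region_labels = NULL,
                        band = NULL,
                        modality = c("electrophysiological",
                                     "haemodynamic")) {
  data <- as.matrix(data)
  modality <- match.arg(modality)
  if (anyNA(data) || !all(is.finite(data))) {
    stop("regional_ts: data contain missing/non-finite values")
  }
  if (nrow(data) < 2 || ncol(data) < 2) {
    stop("regional_ts: need at least 2 regions and 2 samples")
  }
  sampling_rate <- as.numeric(sampling_rate)
  stopifnot(is.finite(sampling_rate), sampling_rate > 0)
  if (!is.null(band) && sampling_rate <= 2 * band$high) {
    stop("regional_ts: sampling rate ", sampling_rate,
         " Hz violates Nyquist for band high edge ", band$high, " Hz")
  }
  if (is.null(region_labels)) {
    region_labels <- rownames(data) %||% paste0("R", seq_len(nrow(data)))
  }
  stopifnot(length(region_labels) == nrow(data))
  rownames(data) <- region_labels
  structure(list(data = data, sampling_rate = sampling_rate,
                 region_labels = region_labels, band = band,
                 modality = modality),
            class = "regional_ts")
}

#' @export
print.regional_ts <- function(x, ...) {
  cat(sprintf("<regional_ts> %d regions x %d samples @ %g Hz (%s)%s\n",
              nrow(x$data), ncol(x$data), x$sampling_rate, x$modality,
              if (!is.null(x$band)) paste0(", band ", x$band$name) else ""))
  invisible(x)
}

#' Zero-phase band-pass filter of regional time series
#'
#' Applies a 4th-order Butterworth band-pass forward and backward
#' (`signal::filtfilt`), giving zero phase distortion so that phase-based
#' connectivity downstream is not biased by filter delay.
#'
#' @param ts A [regional_ts].
#' @param band A [frequency_band]; its high edge must be below Nyquist.
#' @param order Butterworth order (per direction), default 4.
#' @return A [regional_ts] with the `band` field set.
#' @export
bandpass_filter <- function(ts, band, order = 4) {
  stopifnot(inherits(ts, "regional_ts"), inherits(band, "frequency_band"))
  fs <- ts$sampling_rate
  if (fs <= 2 * band$high) {
    stop("bandpass_filter: band high edge ", band$high,
         " Hz at/above Nyquist (fs = ", fs, " Hz)")
  }
  # forward-backward pass needs a comfortable margin over the impulse
  # response; the transient scales with fs/low
  min_len <- 3 * filter_transient(fs, band, order)
  if (ncol(ts$data) < min_len) {
    stop("bandpass_filter: signal too short (", ncol(ts$data),
         " samples; need >= ", min_len, " for band '", band$name, "')")
  }
  bf <- signal::butter(order, c(band$low, band$high) / (fs / 2),
                       type = "pass")
  out <- t(apply(ts$data, 1, function(x) signal::filtfilt(bf, x)))
  rownames(out) <- ts$region_labels
  regional_ts(out, fs, ts$region_labels, band = band,
              modality = ts$modality)
}

#' Filter transient length in samples (edge samples to discard)
#'
#' Three cycles of the band's low edge, a conservative bound on the
#' forward-backward Butterworth settling time.
#' @keywords internal
filter_transient <- function(fs, band, order = 4) {
  ceiling(3 * fs / band$low)
}

#' Analytic signal: instantaneous envelope and phase
#'
#' Computes the discrete analytic signal of each (band-limited) channel by
#' the FFT construction: negative frequencies are zeroed and positive
#' frequencies doubled, leaving DC (and Nyquist, for even lengths)
#' untouched.  The modulus gives the amplitude envelope and the argument
#' the instantaneous phase.
#'
#' @param ts A [regional_ts] (band-limited input expected).
#' @return A list with `envelope` (regions x samples, non-negative),
#'   `phase` (radians in `(-pi, pi]`) and `degenerate` (logical per
#'   region, `TRUE` for zero-variance channels, whose phase is
#'   meaningless).
#' @export
analytic_signal <- function(ts) {
  stopifnot(inherits(ts, "regional_ts"))
  x <- ts$data
  n <- ncol(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  env <- matrix(0, nrow(x), n, dimnames = dimnames(x))
  ph <- env
  degenerate <- apply(x, 1, function(r) stats::var(r) == 0)
  for (i in seq_len(nrow(x))) {
    a <- stats::fft(h * stats::fft(x[i, ]), inverse = TRUE) / n
    env[i, ] <- Mod(a)
    p <- Arg(a)
    p[p <= -pi] <- p[p <= -pi] + 2 * pi   # keep phase in (-pi, pi]
    ph[i, ] <- p
  }
  if (any(degenerate)) {
    warning("analytic_signal: zero-variance channel(s): ",
            paste(ts$region_labels[degenerate], collapse = ", "))
  }
  list(envelope = env, phase = ph, degenerate = degenerate)
}

#' Gaussian distance-weighted ROI aggregation
#'
#' Collapses voxel-level signals within a region to a single
#' representative timecourse, weighting each voxel by
#' `exp(-r^2 / 400)` where `r` is its distance (mm) to the region's
#' centre of mass.  The kernel biases the regional signal towards the
#' centre; at r = 20 mm a voxel's weight has fallen to `exp(-1)`.
#' The weighted sum is unnormalized by default, matching the defining
#' formula; `normalize = TRUE` divides by the summed weights so the
#' output scale is voxel-count invariant.
#'
#' @param voxel_data voxels x samples numeric matrix.
#' @param distances_mm Non-negative per-voxel distances to the centre of
#'   mass, millimetres.
#' @param normalize Divide by the sum of weights? Default `FALSE`.
#' @return Numeric vector of length `samples`.
#' @export
roi_aggregate <- function(voxel_data, distances_mm, normalize = FALSE) {
  voxel_data <- as.matrix(voxel_data)
  distances_mm <- as.numeric(distances_mm)
  if (length(distances_mm) != nrow(voxel_data)) {
    stop("roi_aggregate: ", length(distances_mm), " distances for ",
         nrow(voxel_data), " voxels")
  }
  if (any(!is.finite(distances_mm)) || any(distances_mm < 0)) {
    stop("roi_aggregate: distances must be finite and non-negative")
  }
  w <- roi_kernel(distances_mm)
  out <- as.numeric(crossprod(w, voxel_data))
  if (normalize) out <- out / sum(w)
  out
}

#' The Gaussian ROI weighting kernel exp(-r^2/400)
#'
#' @param r_mm Distance(s) to the region centre of mass, millimetres.
#' @return Weight(s) in `(0, 1]`.
#' @export
roi_kernel <- function(r_mm) exp(-r_mm^2 / 400)
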