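#' Phase lag index of two instantaneous phase traces
#'
#' The PLI measures the asymmetry of the phase-difference distribution:
#' `| mean_t sign(wrap(phi_a(t) - phi_b(t))) |`, with the difference
#' wrapped to `(-pi, pi]`.  It lies in `[0, 1]` and is insensitive to
#' zero-lag coupling: an exactly zero (or pi) phase difference
#' contributes `sign(0) = 0`, so spurious leakage-driven synchrony does
#' not inflate the index.
#'
#' @param phase_a,phase_b Equal-length phase vectors in radians.
#' @return Scalar in `[0, 1]`.
#' @export
pli <- function(phase_a, phase_b) {
  if (length(phase_a) != length(phase_b)) {
    stop("pli: phase vectors differ in length (", length(phase_a),
         " vs ", length(phase_b), ")")
  }
  if (length(phase_a) < 1) stop("pli: empty input")
  d <- phase_a - phase_b
  # wrap to (-pi, pi]; sin keeps the sign of the wrapped difference
  abs(mean(sign(sin(d))))
}

#' Regress one signal out of another (leakage orthogonalization)
#'
#' Removes from `y` its least-squares projection on `x`
#' (`y_perp = y - beta x`, `beta = <x,y>/<x,x>`), so that the residual is
#' exactly orthogonal to `x`.  Used pairwise before envelope correlation
#' to suppress zero-lag signal leakage.
#'
#' @param x Reference signal (nonzero variance required).
#' @param y Signal to orthogonalize.
#' @param tol Relative norm below which `y_perp` is flagged degenerate.
#' @return List with `y_perp` and logical `degenerate` (`TRUE` when `y`
#'   is collinear with `x`).
#' @export
orthogonalize_pair <- function(x, y, tol = 1e-10) {
  stopifnot(length(x) == length(y))
  sxx <- sum(x * x)
  if (sxx == 0) stop("orthogonalize_pair: reference signal is constant zero")
  beta <- sum(x * y) / sxx
  y_perp <- y - beta * x
  ny <- sqrt(sum(y * y))
  degenerate <- ny == 0 || sqrt(sum(y_perp^2)) < tol * ny
  list(y_perp = y_perp, degenerate = degenerate)
}

#' Amplitude envelope correlation of two band-limited signals
#'
#' Pearson correlation between the analytic-signal amplitude envelopes.
#' With `leakage_correction = TRUE` (the default) the estimate is made
#' robust to zero-lag leakage by pairwise symmetric orthogonalization:
#' the correlation of `env(x)` with `env(y` orthogonalized to `x)` is
#' averaged with the correlation of `env(y)` with `env(x` orthogonalized
#' to `y)`.  If the two signals are collinear the orthogonalized residual
#' carries no signal; the AEC is then returned as 0 with a warning so
#' whole-matrix construction never aborts on one bad pair.
#'
#' @param x,y Equal-length band-limited sample vectors.
#' @param leakage_correction Apply symmetric orthogonalization? Default
#'   `TRUE`.
#' @return Scalar in `[-1, 1]` (attribute `degenerate` set when the
#'   collinear fallback triggered).
#' @export
aec <- function(x, y, leakage_correction = TRUE) {
  stopifnot(length(x) == length(y))
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("aec: zero-variance input signal")
  }
  if (!leakage_correction) {
    return(stats::cor(envelope_of(x), envelope_of(y)))
  }
  oy <- orthogonalize_pair(x, y)
  ox <- orthogonalize_pair(y, x)
  if (oy$degenerate || ox$degenerate) {
    warning("aec: collinear pair under leakage correction; returning 0")
    return(structure(0, degenerate = TRUE))
  }
  r1 <- stats::cor(envelope_of(x), envelope_of(oy$y_perp))
  r2 <- stats::cor(envelope_of(y), envelope_of(ox$y_perp))
  (r1 + r2) / 2
}

# analytic-signal envelope of a single vector
envelope_of <- function(x) {
  n <- length(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  Mod(stats::fft(h * stats::fft(x), inverse = TRUE) / n)
}

#' Pearson correlation connectivity matrix
#'
#' Pairwise Pearson correlations between all region pairs; negative
#' correlations are retained.  This is the metric used for the
#' haemodynamic target matrix.
#'
#' @param ts A [regional_ts] with at least 3 samples and no constant
#'   channel.
#' @return A [connectivity_matrix] with `metric = "Pearson"`.
#' @export
pearson_connectivity <- function(ts) {
  stopifnot(inherits(ts, "regional_ts"))
  if (ncol(ts$data) < 3) stop("pearson_connectivity: need >= 3 samples")
  v <- apply(ts$data, 1, stats::var)
  if (any(v == 0)) {
    stop("pearson_connectivity: constant channel(s): ",
         paste(ts$region_labels[v == 0], collapse = ", "))
  }
  r <- stats::cor(t(ts$data))
  diag(r) <- 0
  connectivity_matrix(r, metric = "Pearson", band = ts$band,
                      region_labels = ts$region_labels,
                      symmetrize_tol = 1e-9)
}

#' PLI connectivity matrix from band-limited time series
#'
#' @param ts Band-limited [regional_ts].
#' @param edge_trim Samples discarded at each end before phase statistics
#'   (filter transient); default from the band and sampling rate.
#' @return A [connectivity_matrix] with `metric = "PLI"`.
#' @export
pli_connectivity <- function(ts, edge_trim = NULL) {
  stopifnot(inherits(ts, "regional_ts"))
  an <- analytic_signal(ts)
  keep <- trim_index(ncol(ts$data), ts, edge_trim)
  ph <- an$phase[, keep, drop = FALSE]
  P <- nrow(ph)
  w <- matrix(0, P, P)
  for (i in seq_len(P - 1)) {
    for (j in (i + 1):P) {
      w[i, j] <- w[j, i] <- pli(ph[i, ], ph[j, ])
    }
  }
  connectivity_matrix(w, metric = "PLI", band = ts$band,
                      region_labels = ts$region_labels)
}

#' AEC connectivity matrix from band-limited time series
#'
#' @param ts Band-limited [regional_ts].
#' @param leakage_correction Passed to [aec()]; default `TRUE`.
#' @param edge_trim As in [pli_connectivity()].
#' @return A [connectivity_matrix] with `metric = "AEC"`.
#' @export
aec_connectivity <- function(ts, leakage_correction = TRUE,
                             edge_trim = NULL) {
  stopifnot(inherits(ts, "regional_ts"))
  keep <- trim_index(ncol(ts$data), ts, edge_trim)
  x <- ts$data[, keep, drop = FALSE]
  P <- nrow(x)
  w <- matrix(0, P, P)
  for (i in seq_len(P - 1)) {
    for (j in (i + 1):P) {
      w[i, j] <- w[j, i] <- as.numeric(
        aec(x[i, ], x[j, ], leakage_correction = leakage_correction))
    }
  }
  w[w > 1] <- 1; w[w < -1] <- -1   # guard float spill at +/-1
  connectivity_matrix(w, metric = "AEC", band = ts$band,
                      region_labels = ts$region_labels)
}

trim_index <- function(n, ts, edge_trim) {
  if (is.null(edge_trim)) {
    edge_trim <- if (!is.null(ts$band)) {
      min(filter_transient(ts$sampling_rate, ts$band), floor(n / 10))
    } else 0
  }
  if (2 * edge_trim >= n) stop("edge trim leaves no samples")
  (edge_trim + 1):(n - edge_trim)
}

#' Build a per-(metric, band) connectivity matrix stack
#'
#' Band-pass filters the input once per band and computes one
#' connectivity matrix per requested (metric, band) combination, the
#' input stack for the Taylor model.  Matrices are ordered metric-major
#' (all bands of the first metric, then all bands of the second),
#' mirroring how phase- and amplitude-mode matrices are grouped.
#'
#' @param ts Broadband [regional_ts].
#' @param bands List of [frequency_band] objects (default the five
#'   canonical bands).
#' @param metrics Character subset of `c("pli", "aec")`.
#' @param leakage_correction Passed to [aec_connectivity()].
#' @return A [matrix_stack] of `length(metrics) * length(bands)`
#'   matrices.
#' @export
build_connectivity_stack <- function(ts, bands = canonical_bands(),
                                     metrics = c("pli", "aec"),
                                     leakage_correction = TRUE) {
  stopifnot(inherits(ts, "regional_ts"))
  metrics <- match.arg(tolower(metrics), c("pli", "aec"),
                       several.ok = TRUE)
  if (length(bands) == 0) stop("build_connectivity_stack: no bands")
  filtered <- lapply(bands, function(b) bandpass_filter(ts, b))
  mats <- list()
  for (metric in metrics) {
    for (fb in filtered) {
      m <- if (metric == "pli") pli_connectivity(fb)
           else aec_connectivity(fb, leakage_correction)
      mats[[paste(toupper(metric), fb$band$name, sep = "_")]] <- m
    }
  }
  matrix_stack(mats)
}
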