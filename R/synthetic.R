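#' Specification for synthetic stack-and-target generation
#'
#' Describes the statistical structure the Taylor forward model assumes:
#' a stack of D symmetric zero-diagonal adjacency matrices with entries
#' in `[-1, 1]`, and a target produced from planted coefficients plus
#' symmetric Gaussian noise.
#'
#' @param P Region count (>= 3).
#' @param D Matrix count (>= 1).
#' @param planted_a Length-D vector of linear coefficients (default:
#'   drawn at generation time if `NULL`).
#' @param planted_b Symmetric D x D matrix of quadratic coefficients
#'   (`NULL` for none / drawn).
#' @param planted_c Scalar off-diagonal offset.
#' @param noise_sd Standard deviation of the symmetric Gaussian noise
#'   added to the target's off-diagonal elements (>= 0).
#' @param structure `"random"` (i.i.d. edge weights) or `"modular"`
#'   (two blocks with elevated within-block weights).
#' @param seed Integer seed; the generator is deterministic given it.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(P, D, planted_a = NULL, planted_b = NULL,
                           planted_c = 0, noise_sd = 0,
                           structure = c("random", "modular"),
                           seed = 1) {
  structure <- match.arg(structure)
  P <- as.integer(P); D <- as.integer(D)
  if (P < 3) stop("synthetic_spec: P must be >= 3")
  if (D < 1) stop("synthetic_spec: D must be >= 1")
  if (noise_sd < 0) stop("synthetic_spec: noise_sd must be >= 0")
  if (!is.null(planted_a) && length(planted_a) != D) {
    stop("synthetic_spec: planted_a must have length D = ", D)
  }
  if (!is.null(planted_b)) {
    planted_b <- as.matrix(planted_b)
    if (!identical(dim(planted_b), c(D, D)) ||
        max(abs(planted_b - t(planted_b))) > 1e-12) {
      stop("synthetic_spec: planted_b must be a symmetric D x D matrix")
    }
  }
  base::structure(
    list(P = P, D = D, planted_a = planted_a, planted_b = planted_b,
         planted_c = planted_c, noise_sd = noise_sd,
         structure = structure, seed = as.integer(seed)),
    class = "synthetic_spec")
}

#' Generate a synthetic connectivity-matrix stack
#'
#' D symmetric zero-diagonal matrices with entries in `[-1, 1]`.  With
#' `structure = "random"`, edge weights are i.i.d. uniform on
#' `[-0.5, 0.5]` (a realistic spread for correlation-type weights with
#' both signs retained).  With `structure = "modular"`, regions split
#' into two equal blocks and within-block edges get an additive +0.3
#' elevation before clipping, emulating the block structure of real
#' resting-state matrices.
#'
#' @param spec A [synthetic_spec].
#' @return A [matrix_stack] of matrices `W1..WD`.
#' @export
gen_stack <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(child_seed(spec$seed, 1), {
    P <- spec$P
    mats <- lapply(seq_len(spec$D), function(d) {
      v <- stats::runif(P * (P - 1) / 2, -0.5, 0.5)
      w <- sym_from_upper(v, P)
      if (spec$structure == "modular") {
        block <- rep(1:2, each = ceiling(P / 2))[seq_len(P)]
        same <- outer(block, block, `==`)
        w <- w + 0.3 * same
        diag(w) <- 0
        w <- pmin(pmax(w, -1), 1)
      }
      connectivity_matrix(w, metric = "generic",
                          region_labels = paste0("R", seq_len(P)))
    })
    names(mats) <- paste0("W", seq_len(spec$D))
    matrix_stack(mats)
  })
}

#' Plant a Taylor forward-model target on a stack
#'
#' Builds `V = sum a_m W_m + (1/2) sum_mn b_mn sym(W_m W_n) +
#' c (u u^T - I) + noise` with symmetric Gaussian noise of sd
#' `noise_sd` on the off-diagonal elements and a zeroed diagonal.
#' Coefficients left `NULL` in the spec are drawn (uniform on
#' `[-0.6, 0.6]` for `a`, `[-0.3, 0.3]` for `b`) under the spec's seed.
#' Entries may exceed `[-1, 1]`; they are recorded, not clipped, since
#' clipping would bias coefficient recovery.
#'
#' @param stack A [matrix_stack] of dimension matching the spec.
#' @param spec A [synthetic_spec].
#' @return A [connectivity_matrix] target with attributes `planted`
#'   (list of a, b, c actually used) and `n_out_of_range`.
#' @export
plant_target <- function(stack, spec) {
  stopifnot(inherits(stack, "matrix_stack"),
            inherits(spec, "synthetic_spec"))
  D <- length(stack)
  if (D != spec$D) {
    stop("plant_target: stack has D = ", D, " but spec says ", spec$D)
  }
  W <- lapply(stack$matrices, unclass_cm)
  P <- length(stack$region_labels)
  drawn <- with_seed(child_seed(spec$seed, 2), {
    a <- spec$planted_a %||% stats::runif(D, -0.6, 0.6)
    b <- spec$planted_b
    if (is.null(b)) {
      b <- matrix(stats::runif(D * D, -0.3, 0.3), D, D)
      b <- (b + t(b)) / 2
    }
    noise <- if (spec$noise_sd > 0) {
      sym_from_upper(stats::rnorm(P * (P - 1) / 2, 0, spec$noise_sd), P)
    } else {
      matrix(0, P, P)
    }
    list(a = a, b = b, noise = noise)
  })
  V <- matrix(0, P, P)
  for (m in seq_len(D)) V <- V + drawn$a[m] * W[[m]]
  for (m in seq_len(D)) {
    for (n in seq_len(D)) {
      V <- V + 0.5 * drawn$b[m, n] *
        (W[[m]] %*% W[[n]] + W[[n]] %*% W[[m]]) / 2
    }
  }
  V <- V + spec$planted_c * (matrix(1, P, P) - diag(P))
  V <- V + drawn$noise
  diag(V) <- 0
  out <- connectivity_matrix(V, metric = "generic",
                             region_labels = stack$region_labels,
                             symmetrize_tol = 1e-9)
  attr(out, "planted") <- list(a = drawn$a, b = drawn$b,
                               c = spec$planted_c)
  attr(out, "n_out_of_range") <- sum(abs(upper_tri_vec(V)) > 1)
  out
}

#' Specify planted coupling for oscillatory time-series generation
#'
#' @param band A [frequency_band].
#' @param phase_lag_edges Data frame / matrix with columns `i`, `j`,
#'   `lag` (radians in `(-pi, pi)`, nonzero), or `NULL`.
#' @param envelope_corr_edges Data frame / matrix with columns `i`,
#'   `j`, `rho` (target envelope correlation in `(-1, 1)`), or `NULL`.
#' @return An object of class `coupling_spec`.
#' @export
coupling_spec <- function(band, phase_lag_edges = NULL,
                          envelope_corr_edges = NULL) {
  stopifnot(inherits(band, "frequency_band"))
  chk <- function(e, col, lo, hi) {
    if (is.null(e)) return(NULL)
    e <- as.data.frame(e)
    stopifnot(all(c("i", "j", col) %in% names(e)))
    if (any(e$i == e$j)) stop("coupling_spec: self-edges not allowed")
    if (any(e[[col]] <= lo | e[[col]] >= hi)) {
      stop("coupling_spec: ", col, " must lie in (", lo, ", ", hi, ")")
    }
    e
  }
  pl <- chk(phase_lag_edges, "lag", -pi, pi)
  ec <- chk(envelope_corr_edges, "rho", -1, 1)
  both <- c(
    if (!is.null(pl)) paste(pmin(pl$i, pl$j), pmax(pl$i, pl$j)),
    if (!is.null(ec)) paste(pmin(ec$i, ec$j), pmax(ec$i, ec$j))
  )
  if (anyDuplicated(both)) {
    stop("coupling_spec: conflicting edge definitions on a pair")
  }
  structure(list(band = band, phase_lag_edges = pl,
                 envelope_corr_edges = ec),
            class = "coupling_spec")
}

#' Generate multi-band oscillatory time series with planted coupling
#'
#' Each region's signal is a sum over bands of band-limited noise
#' carriers.  A phase-lag edge makes the pair share one carrier, the
#' second region receiving it with a constant phase shift (applied via
#' the analytic signal) plus a small private carrier, so the phase
#' difference concentrates at the planted lag.  An envelope-correlation
#' edge keeps the carriers independent but replaces their amplitude
#' envelopes by slow log-normal modulators mixed as
#' `sqrt(rho) * common + sqrt(1 - rho) * private` on the log scale, so
#' the planted envelope correlation is approximately `rho` while the
#' phase coupling stays at null.
#'
#' @param specs List of [coupling_spec]s with non-overlapping bands.
#' @param P Number of regions.
#' @param duration_s Recording length in seconds.
#' @param sampling_rate Sampling rate in Hz (must exceed twice the
#'   highest band edge).
#' @param seed Integer seed.
#' @return A [regional_ts] (broadband: sum over the bands).
#' @export
gen_coupled_timeseries <- function(specs, P, duration_s = 300,
                                   sampling_rate = 200, seed = 1) {
  stopifnot(length(specs) >= 1,
            all(vapply(specs, inherits, logical(1), "coupling_spec")))
  edges <- lapply(specs, function(s) c(s$band$low, s$band$high))
  for (a in seq_along(edges)) {
    for (b in seq_along(edges)) {
      if (a < b && edges[[a]][2] > edges[[b]][1] &&
          edges[[b]][2] > edges[[a]][1]) {
        stop("gen_coupled_timeseries: overlapping band definitions")
      }
    }
  }
  hi <- max(vapply(specs, function(s) s$band$high, numeric(1)))
  if (sampling_rate <= 2 * hi) {
    stop("gen_coupled_timeseries: sampling rate below Nyquist for the ",
         "highest band")
  }
  n <- round(duration_s * sampling_rate)
  with_seed(child_seed(seed, 3), {
    out <- matrix(0, P, n)
    for (s in specs) {
      out <- out + band_component(s, P, n, sampling_rate)
    }
    regional_ts(out, sampling_rate,
                region_labels = paste0("R", seq_len(P)))
  })
}

# one band's contribution to all regions
band_component <- function(cs, P, n, fs) {
  bf <- signal::butter(4, c(cs$band$low, cs$band$high) / (fs / 2),
                       type = "pass")
  carrier <- function() signal::filtfilt(bf, stats::rnorm(n))
  comp <- t(vapply(seq_len(P), function(i) carrier(), numeric(n)))
  if (!is.null(cs$phase_lag_edges)) {
    for (k in seq_len(nrow(cs$phase_lag_edges))) {
      e <- cs$phase_lag_edges[k, ]
      shared <- carrier()
      a <- analytic_of(shared)
      # constant phase rotation of the narrowband carrier
      shifted <- Re(a * exp(-1i * e$lag))
      comp[e$i, ] <- shared + 0.2 * carrier()
      comp[e$j, ] <- shifted + 0.2 * carrier()
    }
  }
  if (!is.null(cs$envelope_corr_edges)) {
    slow <- function() {
      # < 1 Hz log-modulator, slow relative to any canonical band
      lp <- signal::butter(2, min(0.5, cs$band$low / 4) / (fs / 2),
                           type = "low")
      g <- signal::filtfilt(lp, stats::rnorm(n))
      g / stats::sd(g)
    }
    # smooth-phase carrier: centre frequency with slow band-limited
    # frequency wander, so the analytic envelope is carried entirely by
    # the imposed modulator (band-limited noise carriers would re-inject
    # envelope fluctuations of their own and dilute the planted
    # correlation)
    fm_carrier <- function() {
      fc <- (cs$band$low + cs$band$high) / 2
      df <- 0.3 * (cs$band$high - cs$band$low) / 2
      f_inst <- fc + df * slow()
      cos(2 * pi * cumsum(f_inst) / fs + stats::runif(1, 0, 2 * pi))
    }
    sigma <- 0.5
    # mix on the log scale at the correlation that makes the lognormal
    # modulators correlate at exactly the target rho
    rho_g <- log(1 + cs$envelope_corr_edges$rho * (exp(sigma^2) - 1)) /
      sigma^2
    rho_g <- pmin(pmax(rho_g, -1), 1)
    for (k in seq_len(nrow(cs$envelope_corr_edges))) {
      e <- cs$envelope_corr_edges[k, ]
      g0 <- slow()
      sgn <- c(1, sign(rho_g[k]))
      ar <- sqrt(abs(rho_g[k]))
      for (idx in 1:2) {
        r <- c(e$i, e$j)[idx]
        z <- ar * sgn[idx] * g0 + sqrt(1 - abs(rho_g[k])) * slow()
        m <- exp(sigma * z)
        comp[r, ] <- fm_carrier() * m
      }
    }
  }
  comp
}

analytic_of <- function(x) {
  n <- length(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(h * stats::fft(x), inverse = TRUE) / n
}

#' Coefficient-recovery experiment
#'
#' Generates `n_replicates` independent (stack, target) pairs under the
#' spec, fits the matching Taylor model, and reports per-replicate
#' coefficient errors and R^2 with summary medians and quartiles.
#'
#' @param spec A [synthetic_spec] (its seed is the base; replicate k
#'   uses `child_seed(seed, 100 + k)`).
#' @param n_replicates Number of replicates.
#' @return An object of class `recovery_report`: data.frame `replicates`
#'   (seed, max_rel_err, r2), `summary` (medians/quartiles),
#'   `n_coefficients` (hessian and distinct conventions).
#' @export
recovery_experiment <- function(spec, n_replicates = 20) {
  stopifnot(inherits(spec, "synthetic_spec"), n_replicates >= 1)
  model <- model_spec(if (spec$D == 1) "single_frequency"
                      else "nonlinear_cross")
  rows <- lapply(seq_len(n_replicates), function(k) {
    sk <- child_seed(spec$seed, 100 + k)
    spk <- synthetic_spec(spec$P, spec$D, spec$planted_a,
                          spec$planted_b, spec$planted_c,
                          spec$noise_sd, spec$structure, seed = sk)
    stk <- gen_stack(spk)
    V <- plant_target(stk, spk)
    fit <- fit_taylor(V, stk, model)
    planted <- attr(V, "planted")
    truth <- c(planted$a, planted$b[upper.tri(planted$b, diag = TRUE)],
               planted$c)
    est <- c(fit$a,
             if (!is.null(fit$b)) fit$b[upper.tri(fit$b, diag = TRUE)],
             fit$c)
    rel <- abs(est - truth) / pmax(abs(truth), 1e-8)
    data.frame(seed = sk, max_rel_err = max(rel),
               median_rel_err = stats::median(rel), r2 = fit$r2)
  })
  reps <- do.call(rbind, rows)
  structure(list(
    replicates = reps,
    summary = data.frame(
      quantity = c("max_rel_err", "r2"),
      median = c(stats::median(reps$max_rel_err), stats::median(reps$r2)),
      q25 = c(stats::quantile(reps$max_rel_err, 0.25),
              stats::quantile(reps$r2, 0.25)),
      q75 = c(stats::quantile(reps$max_rel_err, 0.75),
              stats::quantile(reps$r2, 0.75))
    ),
    n_coefficients = list(
      hessian = count_coefficients(spec$D, "hessian"),
      distinct = count_coefficients(spec$D, "distinct")
    ),
    spec = spec
  ), class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf(
    "<recovery_report> P = %d, D = %d, noise_sd = %g, %d replicates\n",
    x$spec$P, x$spec$D, x$spec$noise_sd, nrow(x$replicates)))
  cat(sprintf("  median max relative error: %.3g; median R^2: %.4f\n",
              x$summary$median[1], x$summary$median[2]))
  cat(sprintf("  coefficients: %d (hessian convention), %d (distinct)\n",
              x$n_coefficients$hessian$total, x$n_coefficients$distinct$total))
  invisible(x)
}
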