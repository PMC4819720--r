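#' Spectrum-preserving pseudo-matrix surrogate
#'
#' Builds a surrogate adjacency matrix sharing the eigenvalue spectrum
#' of the input but with randomized eigenvectors, the null model for the
#' permutation tests.  The input is eigendecomposed `W = U L U^T`; each
#' eigenvector's entry sequence is Fourier phase-randomized (random
#' Hermitian-symmetric phases, amplitude spectrum preserved), the
#' randomized vectors are re-orthonormalized by QR, and the matrix is
#' reconstructed as `U' L U'^T`.  Because `U'` is orthonormal the
#' eigenvalue multiset is preserved exactly; the diagonal is then zeroed
#' so the surrogate satisfies the adjacency-matrix invariants (this
#' perturbs the spectrum slightly, as it does for the real matrices'
#' construction).
#'
#' @param W A symmetric [connectivity_matrix] (or plain symmetric
#'   matrix).
#' @param seed Integer seed (the surrogate is deterministic given it),
#'   or `NULL` to draw from the current RNG stream.
#' @param zero_diagonal Zero the reconstructed diagonal (default
#'   `TRUE`)?  `FALSE` returns the raw similarity-transformed matrix,
#'   whose eigenvalue multiset equals the input's exactly.
#' @return A [connectivity_matrix] with `metric = "generic"` (a plain
#'   symmetric matrix when `zero_diagonal = FALSE`).
#' @export
pseudo_matrix <- function(W, seed = NULL, zero_diagonal = TRUE) {
  labels <- rownames(W)
  w <- as.matrix(W)
  if (max(abs(w - t(w))) > 1e-10) {
    stop("pseudo_matrix: input must be symmetric")
  }
  build <- function() {
    ed <- eigen(w, symmetric = TRUE)
    U <- ed$vectors
    Ur <- apply(U, 2, phase_randomize)
    Uq <- qr.Q(qr(Ur))
    out <- Uq %*% (ed$values * t(Uq))
    (out + t(out)) / 2
  }
  out <- if (is.null(seed)) build() else with_seed(seed, build())
  if (!zero_diagonal) {
    dimnames(out) <- list(labels, labels)
    return(out)
  }
  diag(out) <- 0
  connectivity_matrix(out, metric = "generic", region_labels = labels,
                      symmetrize_tol = 1e-9)
}

# Fourier phase randomization of a real sequence: random phases applied
# with Hermitian symmetry so the result is real with the same amplitude
# spectrum (DC and Nyquist bins kept real).
phase_randomize <- function(x) {
  n <- length(x)
  if (n < 3) return(x)
  X <- stats::fft(x)
  half <- floor((n - 1) / 2)
  ph <- stats::runif(half, 0, 2 * pi)
  rot <- rep(0, n)
  rot[2:(half + 1)] <- ph
  rot[n:(n - half + 1)] <- -ph
  Re(stats::fft(X * exp(1i * rot), inverse = TRUE) / n)
}

#' Generate a pseudo-stack (one surrogate per matrix)
#'
#' @param stack A [matrix_stack].
#' @param seed Seed expanded to one child seed per matrix, or `NULL`.
#' @return A [matrix_stack] of surrogates with the original names.
#' @export
pseudo_stack <- function(stack, seed = NULL) {
  stopifnot(inherits(stack, "matrix_stack"))
  mats <- lapply(seq_along(stack$matrices), function(k) {
    s <- if (is.null(seed)) NULL else child_seed(seed, k)
    pseudo_matrix(stack$matrices[[k]], seed = s)
  })
  names(mats) <- names(stack$matrices)
  matrix_stack(mats)
}

perm_result <- function(observed, null_values, seed, statistic_name,
                        alternative = "greater") {
  n_perm <- length(null_values)
  exceed <- if (alternative == "greater") sum(null_values >= observed)
            else sum(null_values <= observed)
  p <- (1 + exceed) / (1 + n_perm)
  structure(list(observed = observed, null_values = null_values,
                 p_value = p, n_perm = n_perm, seed = seed,
                 statistic_name = statistic_name,
                 alternative = alternative),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf(
    "<permutation_result> %s: observed = %.4g, p = %.4g (%d permutations)\n",
    x$statistic_name, x$observed, x$p_value, x$n_perm))
  cat(sprintf("  null: mean %.4g, sd %.4g, 95th pct %.4g\n",
              mean(x$null_values), stats::sd(x$null_values),
              stats::quantile(x$null_values, 0.95)))
  invisible(x)
}

#' Permutation test of variance explained (Test 1)
#'
#' Does the real stack predict significant variance in the target?  The
#' observed statistic is the R^2 of the fit on the real stack; the null
#' distribution is built from R^2 of fits on a fresh pseudo-stack per
#' iteration.  The one-sided p-value uses the add-one rule
#' `(1 + exceedances) / (1 + n_perm)`, so it can never be exactly zero.
#' The Bonferroni-adjusted threshold for running this test over the five
#' model variants (0.05 / 5) is attached.
#'
#' @param V Target [connectivity_matrix].
#' @param stack A [matrix_stack].
#' @param spec A [model_spec].
#' @param n_perm Number of permutations (>= 1); default 1000.
#' @param seed Integer seed.
#' @param n_tests Number of model variants the Bonferroni threshold
#'   accounts for; default 5.
#' @return A `permutation_result` with extra fields `bonferroni_alpha`
#'   and `significant`.
#' @export
test_variance_explained <- function(V, stack, spec, n_perm = 1000,
                                    seed = 1, n_tests = 5) {
  if (n_perm < 1) stop("test_variance_explained: n_perm must be >= 1")
  observed <- fit_taylor(V, stack, spec)$r2
  null_values <- vapply(seq_len(n_perm), function(i) {
    ps <- pseudo_stack(stack, seed = child_seed(seed, i))
    fit_taylor(V, ps, spec)$r2
  }, numeric(1))
  res <- perm_result(observed, null_values, seed, "R^2")
  res$bonferroni_alpha <- 0.05 / n_tests
  res$significant <- res$p_value < res$bonferroni_alpha
  res
}

#' Permutation test of the complexity gradient (Test 2a)
#'
#' Measures the rate of improvement of R^2 with increasing model
#' complexity: the least-squares slope of R^2 against model index over
#' the ordered nested sequence.  Pseudo-stacks also gain R^2 with added
#' terms, so the null slopes are positive too; the test asks whether the
#' real rate of improvement exceeds what surrogate structure produces.
#' One pseudo-stack is drawn per iteration and shared across the models,
#' preserving within-iteration nesting.
#'
#' @param V Target matrix.
#' @param stack A [matrix_stack].
#' @param ordered_specs Ordered list of >= 2 nested [model_spec]s.
#' @param n_perm,seed As in [test_variance_explained()].
#' @return A `permutation_result` (statistic `"R^2 gradient"`, extra
#'   field `observed_r2` with the per-model R^2 sequence).
#' @export
test_gradient <- function(V, stack, ordered_specs, n_perm = 1000,
                          seed = 1) {
  if (length(ordered_specs) < 2) {
    stop("test_gradient: need at least 2 ordered models")
  }
  if (n_perm < 1) stop("test_gradient: n_perm must be >= 1")
  r2_seq <- function(stk) {
    vapply(ordered_specs,
           function(sp) fit_taylor(V, stk, sp)$r2, numeric(1))
  }
  obs_r2 <- r2_seq(stack)
  observed <- r2_slope(obs_r2)
  null_values <- vapply(seq_len(n_perm), function(i) {
    r2_slope(r2_seq(pseudo_stack(stack, seed = child_seed(seed, i))))
  }, numeric(1))
  res <- perm_result(observed, null_values, seed, "R^2 gradient")
  res$observed_r2 <- obs_r2
  res
}

# least-squares slope of y against index 1..length(y)
r2_slope <- function(y) {
  x <- seq_along(y)
  sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
}

#' Permutation tests of successive model increments (Test 2b)
#'
#' For each step up the nested sequence, tests whether the increase in
#' R^2 between successive models exceeds the increase produced by
#' pseudo-stacks.  Significance thresholds are Bonferroni-corrected for
#' the number of increments (0.05 / 3 for the standard four-model
#' sequence).
#'
#' @inheritParams test_gradient
#' @return List of `permutation_result`s, one per increment, each with
#'   `bonferroni_alpha` and `significant` fields.
#' @export
test_increments <- function(V, stack, ordered_specs, n_perm = 1000,
                            seed = 1) {
  if (length(ordered_specs) < 2) {
    stop("test_increments: need at least 2 ordered nested models")
  }
  if (n_perm < 1) stop("test_increments: n_perm must be >= 1")
  r2_seq <- function(stk) {
    vapply(ordered_specs,
           function(sp) fit_taylor(V, stk, sp)$r2, numeric(1))
  }
  obs_inc <- diff(r2_seq(stack))
  n_inc <- length(obs_inc)
  null_inc <- matrix(NA_real_, n_perm, n_inc)
  for (i in seq_len(n_perm)) {
    null_inc[i, ] <-
      diff(r2_seq(pseudo_stack(stack, seed = child_seed(seed, i))))
  }
  alpha <- 0.05 / n_inc
  lapply(seq_len(n_inc), function(k) {
    res <- perm_result(obs_inc[k], null_inc[, k], seed,
                       sprintf("delta R^2 (model %d -> %d)", k, k + 1))
    res$bonferroni_alpha <- alpha
    res$significant <- res$p_value < alpha
    res
  })
}

#' Subject-swap permutation test (subject-level specificity)
#'
#' Asks whether a subject's own electrophysiological stack predicts
#' their haemodynamic matrix better than other subjects' stacks.  The
#' observed statistic per subject is the matched-pair R^2; the null
#' draws, per iteration, a non-matching subject's stack at random.
#'
#' @param per_subject_V List of >= 3 target matrices.
#' @param per_subject_stacks List of matching [matrix_stack]s.
#' @param spec A [model_spec].
#' @param n_perm Number of permutations (>= 1); default 1000.
#' @param seed Integer seed.
#' @param alpha Per-subject significance level, default 0.05.
#' @return List of `permutation_result`s, one per subject, each with a
#'   `significant` field.
#' @export
subject_swap_test <- function(per_subject_V, per_subject_stacks, spec,
                              n_perm = 1000, seed = 1, alpha = 0.05) {
  S <- length(per_subject_V)
  if (S < 3) stop("subject_swap_test: need at least 3 subjects")
  if (length(per_subject_stacks) != S) {
    stop("subject_swap_test: ", S, " targets but ",
         length(per_subject_stacks), " stacks")
  }
  if (n_perm < 1) stop("subject_swap_test: n_perm must be >= 1")
  lapply(seq_len(S), function(s) {
    observed <- fit_taylor(per_subject_V[[s]], per_subject_stacks[[s]],
                           spec)$r2
    others <- setdiff(seq_len(S), s)
    null_values <- with_seed(child_seed(seed, s), {
      picks <- sample(others, n_perm, replace = TRUE)
      vapply(picks, function(o) {
        fit_taylor(per_subject_V[[s]], per_subject_stacks[[o]], spec)$r2
      }, numeric(1))
    })
    res <- perm_result(observed, null_values, seed,
                       sprintf("subject %d matched R^2", s))
    res$significant <- res$p_value < alpha
    res
  })
}

#' Mann-Whitney U test (normal approximation with tie correction)
#'
#' Rank-sum comparison of two independent samples, with midranks for
#' ties, the tie-corrected normal approximation for Z, and a two-sided
#' p-value.  For small samples without ties `exact = TRUE` computes the
#' p-value by exhaustive enumeration of all group assignments.
#'
#' @param sample_a,sample_b Non-empty numeric vectors.
#' @param exact Enumerate the exact null distribution of U? Default
#'   `FALSE` (normal approximation, as used for reporting Z).
#' @return List with `U` (for `sample_a`), `Z`, `p`.
#' @export
mann_whitney_u <- function(sample_a, sample_b, exact = FALSE) {
  na <- length(sample_a); nb <- length(sample_b)
  if (na == 0 || nb == 0) stop("mann_whitney_u: empty sample")
  pooled <- c(sample_a, sample_b)
  r <- rank(pooled)                       # midranks for ties
  Ra <- sum(r[seq_len(na)])
  U <- Ra - na * (na + 1) / 2             # #{a_i > b_j} + ties/2
  mu <- na * nb / 2
  n <- na + nb
  ties <- table(pooled)
  tie_corr <- sum(ties^3 - ties) / (n * (n - 1))
  sigma2 <- na * nb / 12 * (n + 1 - tie_corr)
  Z <- if (sigma2 > 0) (U - mu) / sqrt(sigma2) else 0
  if (exact) {
    if (any(duplicated(pooled))) {
      warning("mann_whitney_u: ties present; exact enumeration uses ",
              "midrank U values")
    }
    combs <- utils::combn(n, na)
    u_null <- apply(combs, 2, function(idx) {
      sum(r[idx]) - na * (na + 1) / 2
    })
    p <- mean(abs(u_null - mu) >= abs(U - mu) - 1e-12)
  } else {
    p <- 2 * stats::pnorm(-abs(Z))
    p <- min(p, 1)
  }
  list(U = U, Z = Z, p = p)
}

#' Regional contribution of one input matrix (single-frequency view)
#'
#' Fits the single-frequency model for one (band, metric) matrix and
#' summarizes which region pairs that band explains: the fitted edges
#' are ranked by absolute predicted weight and the top
#' `round(R^2 * E)` edges retained (an R^2 of 0.1 retains the top 10%
#' of the E = P(P-1)/2 edges).  Ties in the ranking are broken by
#' region-label lexicographic order for determinism.  Node strength is
#' the per-region mean of the fitted matrix's off-diagonal entries.
#'
#' @param V Target [connectivity_matrix].
#' @param stack A [matrix_stack].
#' @param band Band name to select (used with `metric` against the
#'   stack's index), or `NULL` if `matrix_name` is given.
#' @param metric Metric name, or `NULL`.
#' @param matrix_name Direct stack matrix name (alternative selection).
#' @return An object of class `regional_contribution`: `band`, `metric`,
#'   `r2`, `n_retained`, `retained_edges` (data.frame region_a,
#'   region_b, weight), `node_strength` (named vector), `fit`.
#' @export
regional_contribution <- function(V, stack, band = NULL, metric = NULL,
                                  matrix_name = NULL) {
  spec <- if (!is.null(matrix_name)) {
    model_spec("single_frequency", matrices = matrix_name)
  } else {
    model_spec("single_frequency", bands = band, metrics = metric)
  }
  fit <- fit_taylor(V, stack, spec)
  P <- nrow(fit$fitted)
  E <- P * (P - 1) / 2
  labels <- rownames(fit$fitted)
  iu <- which(upper.tri(fit$fitted), arr.ind = TRUE)
  edges <- data.frame(
    region_a = labels[iu[, 1]], region_b = labels[iu[, 2]],
    weight = fit$fitted[iu], stringsAsFactors = FALSE
  )
  n_keep <- if (fit$r2 <= 0) 0L else as.integer(round(fit$r2 * E))
  if (n_keep == 0L) {
    warning("regional_contribution: R^2 <= 0 (or rounds to zero edges); ",
            "empty result")
    retained <- edges[0, ]
  } else {
    ord <- order(-abs(edges$weight), edges$region_a, edges$region_b)
    retained <- edges[ord[seq_len(n_keep)], ]
    rownames(retained) <- NULL
  }
  strength <- rowSums(fit$fitted) / (P - 1)
  structure(list(band = band, metric = metric, r2 = fit$r2,
                 n_retained = n_keep, retained_edges = retained,
                 node_strength = strength, fit = fit),
            class = "regional_contribution")
}

#' @export
print.regional_contribution <- function(x, ...) {
  cat(sprintf(
    "<regional_contribution> %s%s: R^2 = %.4f, %d edges retained\n",
    x$metric %||% "", if (!is.null(x$band)) paste0("/", x$band) else "",
    x$r2, x$n_retained))
  invisible(x)
}
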