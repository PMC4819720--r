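#' Specify a Taylor-expansion model variant
#'
#' The nested model family maps onto progressively richer truncations of
#' the multivariate expansion of the target matrix in the input stack:
#'
#' * `single_frequency` - one matrix, linear term only;
#' * `linear` - all selected matrices, linear terms only ("direct
#'   connectivity");
#' * `nonlinear` - linear plus within-matrix quadratic terms `W_m^2`
#'   ("shared connectivity"), cross products excluded;
#' * `nonlinear_cross` - additionally the symmetrized cross products
#'   between different matrices of one metric;
#' * `full` - both coupling metrics, all linear, quadratic and cross
#'   terms.
#'
#' The expansion is developed at zero (the natural point: connectivity
#' matrices have zero trace so their eigenvalues are centred there).
#'
#' @param variant One of the five variant names.
#' @param bands Optional character vector of band names to select from a
#'   stack (required: exactly one for `single_frequency`).
#' @param metrics Optional character vector of metric names (`"PLI"`,
#'   `"AEC"`); exactly one for the single-metric variants when the stack
#'   mixes metrics.
#' @param matrices Optional character vector of stack matrix names to
#'   select directly, for stacks without band/metric metadata.
#' @return An object of class `model_spec` with derived flags
#'   `include_quadratic`, `include_cross_terms`.
#' @export
model_spec <- function(variant = c("single_frequency", "linear",
                                   "nonlinear", "nonlinear_cross",
                                   "full"),
                       bands = NULL, metrics = NULL, matrices = NULL) {
  variant <- match.arg(variant)
  include_quadratic <- variant %in% c("nonlinear", "nonlinear_cross",
                                      "full")
  include_cross_terms <- variant %in% c("nonlinear_cross", "full")
  if (variant == "single_frequency") {
    if (!is.null(bands) && length(bands) != 1) {
      stop("model_spec: single_frequency needs exactly one band")
    }
    if (!is.null(matrices) && length(matrices) != 1) {
      stop("model_spec: single_frequency needs exactly one matrix")
    }
  }
  if (variant == "full" && !is.null(metrics) && length(metrics) < 2) {
    stop("model_spec: full model uses both metrics")
  }
  structure(list(variant = variant, bands = bands, metrics = metrics,
                 matrices = matrices,
                 include_quadratic = include_quadratic,
                 include_cross_terms = include_cross_terms,
                 development_point = 0),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("<model_spec> %s (quadratic: %s, cross-terms: %s)\n",
              x$variant, x$include_quadratic, x$include_cross_terms))
  if (!is.null(x$bands)) cat("  bands:", paste(x$bands, collapse = ", "), "\n")
  if (!is.null(x$metrics)) cat("  metrics:", paste(x$metrics, collapse = ", "), "\n")
  invisible(x)
}

#' Select the stack matrices a model spec refers to
#'
#' Filters by the spec's `metrics` and `bands` where the stack carries
#' that metadata; a spec with neither set uses the whole stack.
#'
#' @param stack A [matrix_stack].
#' @param spec A [model_spec].
#' @return A [matrix_stack].
#' @export
select_stack <- function(stack, spec) {
  stopifnot(inherits(stack, "matrix_stack"), inherits(spec, "model_spec"))
  keep <- rep(TRUE, length(stack$matrices))
  if (!is.null(spec$metrics)) {
    keep <- keep & toupper(stack$index$metric) %in% toupper(spec$metrics)
  }
  if (!is.null(spec$bands)) {
    keep <- keep & stack$index$band %in% spec$bands
  }
  if (!is.null(spec$matrices)) {
    keep <- keep & stack$index$name %in% spec$matrices
  }
  if (!any(keep)) stop("select_stack: spec matches no matrix in the stack")
  sub <- matrix_stack(stack$matrices[keep])
  if (spec$variant == "single_frequency" && length(sub) != 1) {
    stop("select_stack: single_frequency must resolve to one matrix, got ",
         length(sub))
  }
  sub
}

#' Build the Taylor regressor terms for a stack and model spec
#'
#' Linear regressors are the selected matrices `W_m` themselves.
#' Quadratic regressors implement the second-order terms with the 1/2
#' factor of the expansion kept in the regressor, so the estimated
#' coefficients are the Hessian entries `b_mn` directly:
#' `R_mm = W_m^2 / 2` for within-matrix terms and
#' `R_mn = (W_m W_n + W_n W_m) / 2` for each unordered cross pair
#' (one coefficient per pair; a symmetric Hessian loses no generality on
#' a symmetric target).  A constant regressor of ones models the
#' off-diagonal offset `c (u u^T - I)`.  All regressors are vectorized
#' over the `E = P(P-1)/2` upper-triangle off-diagonal elements.
#'
#' @param stack A [matrix_stack] (already selected for the spec, or a
#'   full stack which will be passed through [select_stack()]).
#' @param spec A [model_spec].
#' @return An object of class `term_list`: `regressors` (named list of
#'   P x P matrices), `design` (E x K numeric matrix, offset column
#'   last), `linear_names`, `quad_pairs` (2-column character matrix),
#'   `region_labels`.
#' @export
build_terms <- function(stack, spec) {
  stopifnot(inherits(stack, "matrix_stack"), inherits(spec, "model_spec"))
  sel <- select_stack(stack, spec)
  W <- lapply(sel$matrices, unclass_cm)
  D <- length(W)
  nm <- names(W)
  regs <- W
  quad_pairs <- matrix(character(0), ncol = 2)
  if (spec$include_quadratic) {
    for (m in seq_len(D)) {
      regs[[paste(nm[m], nm[m], sep = ":")]] <- (W[[m]] %*% W[[m]]) / 2
      quad_pairs <- rbind(quad_pairs, c(nm[m], nm[m]))
    }
    if (spec$include_cross_terms && D > 1) {
      for (m in seq_len(D - 1)) {
        for (n in (m + 1):D) {
          regs[[paste(nm[m], nm[n], sep = ":")]] <-
            (W[[m]] %*% W[[n]] + W[[n]] %*% W[[m]]) / 2
          quad_pairs <- rbind(quad_pairs, c(nm[m], nm[n]))
        }
      }
    }
  }
  E <- length(upper_tri_vec(W[[1]]))
  design <- vapply(regs, upper_tri_vec, numeric(E))
  design <- cbind(design, offset = rep(1, E))
  structure(list(regressors = regs, design = design,
                 linear_names = nm, quad_pairs = quad_pairs,
                 region_labels = sel$region_labels, spec = spec),
            class = "term_list")
}

#' Count Taylor coefficients for a model of dimension D
#'
#' Two conventions: `"hessian"` counts every gradient entry (D) plus
#' every entry of the full D x D Hessian (so D + D^2 when cross terms
#' are in play, e.g. 110 for D = 10, the count usually quoted for a
#' two-metric five-band model); `"distinct"` counts the distinct
#' coefficients actually estimated under the symmetric-Hessian
#' parameterization, D + D(D+1)/2.  The off-diagonal offset is excluded
#' from both counts.
#'
#' @param D Number of input matrices.
#' @param convention `"hessian"` or `"distinct"`.
#' @param include_quadratic,include_cross_terms Model flags, default
#'   both `TRUE` (the cross-term and full models).
#' @return List with `linear`, `quadratic`, `total`.
#' @export
count_coefficients <- function(D, convention = c("hessian", "distinct"),
                               include_quadratic = TRUE,
                               include_cross_terms = TRUE) {
  convention <- match.arg(convention)
  D <- as.integer(D)
  stopifnot(D >= 1)
  quad <- if (!include_quadratic) 0L
          else if (!include_cross_terms) D
          else if (convention == "hessian") D * D
          else (D * (D + 1L)) %/% 2L
  list(linear = D, quadratic = as.integer(quad),
       total = as.integer(D + quad))
}
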