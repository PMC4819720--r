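#' Matrix product of two connectivity matrices ("shared connectivity")
#'
#' The ordinary matrix product `Wm %*% Wn`.  Entry (p, q) is the inner
#' product of column p of `Wm` with column q of `Wn`: the unnormalized
#' covariance between region p's whole-brain connectivity profile in one
#' matrix and region q's profile in the other.  Its diagonal holds the
#' unnormalized variance of each column.  These products are the
#' quadratic (shared-connectivity) terms of the expansion.
#'
#' @param Wm,Wn [connectivity_matrix] objects (or plain symmetric
#'   matrices) with identical region labels.
#' @return A plain P x P matrix (generally asymmetric when `Wm != Wn`).
#' @export
shared_connectivity <- function(Wm, Wn) {
  Wm <- as.matrix(Wm); Wn <- as.matrix(Wn)
  if (!identical(dim(Wm), dim(Wn))) {
    stop("shared_connectivity: dimension mismatch (",
         paste(dim(Wm), collapse = "x"), " vs ",
         paste(dim(Wn), collapse = "x"), ")")
  }
  if (!is.null(rownames(Wm)) && !is.null(rownames(Wn)) &&
      !identical(rownames(Wm), rownames(Wn))) {
    stop("shared_connectivity: region labels differ")
  }
  Wm %*% Wn
}

#' Fit Taylor coefficients by least squares
#'
#' Estimates the linear coefficients `a_m`, quadratic coefficients
#' `b_mn` and off-diagonal offset `c` that minimize the sum of squared
#' residuals between the target matrix and the expansion, over the
#' E = P(P-1)/2 unique off-diagonal elements.  The expansion is linear
#' in its coefficients once the matrix products are precomputed, so the
#' optimum is found deterministically by ordinary least squares (QR);
#' an iterative optimizer (`method = "iterative"`, Gauss-Newton via
#' [stats::optim] BFGS on the same objective) is available and converges
#' to the same optimum.  Confidence intervals are the classical
#' two-sided 95% intervals from the linear-model covariance of the
#' estimates.  A rank-deficient design is reported with the offending
#' regressor labels and solved by the minimum-norm (pseudo-inverse)
#' solution with a warning.
#'
#' @param V Target [connectivity_matrix].
#' @param terms A `term_list` from [build_terms()], or a [matrix_stack]
#'   (in which case `spec` must be given).
#' @param spec Optional [model_spec] when `terms` is a stack.
#' @param method `"ols"` (default) or `"iterative"`.
#' @param conf_level Confidence level for the coefficient intervals.
#' @return An object of class `taylor_fit`: `a` (named linear
#'   coefficients), `b` (symmetric named matrix of quadratic
#'   coefficients, `NULL` if none), `c` (offset), `coefficients` (full
#'   named vector), `fitted` (P x P symmetric, zero diagonal),
#'   `residual` matrix, `r2`, `ci` (K x 2), `sigma`, `spec`,
#'   `term_names`, `rank_deficient`, `out_of_range` (count of fitted
#'   entries outside [-1, 1]).
#' @export
fit_taylor <- function(V, terms, spec = NULL, method = c("ols", "iterative"),
                       conf_level = 0.95) {
  method <- match.arg(method)
  if (inherits(terms, "matrix_stack")) {
    if (is.null(spec)) stop("fit_taylor: spec required with a raw stack")
    terms <- build_terms(terms, spec)
  }
  stopifnot(inherits(terms, "term_list"))
  if (!identical(region_labels(V), terms$region_labels)) {
    stop("fit_taylor: target and terms disagree on region labels")
  }
  X <- terms$design
  y <- upper_tri_vec(V)
  E <- length(y); K <- ncol(X)
  if (K >= E) {
    stop("fit_taylor: ", K, " coefficients for only ", E,
         " unique off-diagonal elements")
  }
  qrX <- qr(X)
  rank_deficient <- qrX$rank < K
  if (rank_deficient) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):K]]
    warning("fit_taylor: rank-deficient design (collinear regressors: ",
            paste(dropped, collapse = ", "),
            "); using minimum-norm solution")
    sv <- svd(X)
    pos <- sv$d > max(sv$d) * 1e-12
    beta <- sv$v[, pos, drop = FALSE] %*%
      ((crossprod(sv$u[, pos, drop = FALSE], y)) / sv$d[pos])
    beta <- drop(beta)
  } else {
    beta <- qr.coef(qrX, y)
  }
  names(beta) <- colnames(X)
  if (method == "iterative") {
    # same least-squares objective, minimized iteratively; the linear
    # problem is convex so this lands on the OLS optimum
    obj <- function(b) sum((y - X %*% b)^2)
    grad <- function(b) -2 * drop(crossprod(X, y - X %*% b))
    opt <- stats::optim(rep(0, K), obj, grad, method = "BFGS",
                        control = list(maxit = 1000, reltol = 1e-14))
    beta <- opt$par
    names(beta) <- colnames(X)
  }
  yhat <- drop(X %*% beta)
  res <- y - yhat
  sst <- sum((y - mean(y))^2)
  if (sst == 0) stop("fit_taylor: constant target matrix, R^2 undefined")
  r2 <- 1 - sum(res^2) / sst
  dfres <- E - qrX$rank
  sigma2 <- sum(res^2) / dfres
  ci <- matrix(NA_real_, K, 2,
               dimnames = list(colnames(X), c("lower", "upper")))
  if (!rank_deficient) {
    op <- order(qrX$pivot)
    XtXinv <- chol2inv(qr.R(qrX))[op, op, drop = FALSE]
    se <- sqrt(pmax(diag(XtXinv), 0) * sigma2)
    tq <- stats::qt(1 - (1 - conf_level) / 2, dfres)
    ci[, 1] <- beta - tq * se
    ci[, 2] <- beta + tq * se
  }
  P <- length(terms$region_labels)
  fitted <- sym_from_upper(yhat, P, terms$region_labels)
  residual <- sym_from_upper(res, P, terms$region_labels)
  a <- beta[terms$linear_names]
  b <- NULL
  if (nrow(terms$quad_pairs) > 0) {
    nm <- terms$linear_names
    b <- matrix(NA_real_, length(nm), length(nm), dimnames = list(nm, nm))
    for (k in seq_len(nrow(terms$quad_pairs))) {
      i <- terms$quad_pairs[k, 1]; j <- terms$quad_pairs[k, 2]
      b[i, j] <- b[j, i] <-
        beta[paste(i, j, sep = ":")]
    }
  }
  structure(list(a = a, b = b, c = unname(beta["offset"]),
                 coefficients = beta, fitted = fitted,
                 residual = residual, r2 = r2, ci = ci,
                 sigma = sqrt(sigma2), spec = terms$spec,
                 term_names = colnames(X),
                 rank_deficient = rank_deficient,
                 out_of_range = sum(abs(yhat) > 1)),
            class = "taylor_fit")
}

#' @export
print.taylor_fit <- function(x, ...) {
  cat(sprintf("<taylor_fit> %s: %d coefficients (+offset), R^2 = %.4f\n",
              x$spec$variant,
              length(x$coefficients) - 1L, x$r2))
  if (x$out_of_range > 0) {
    cat("  note:", x$out_of_range,
        "fitted entries outside [-1, 1] (not clipped)\n")
  }
  invisible(x)
}

#' Predict the target matrix from a fitted expansion
#'
#' Applies the estimated coefficients to a (possibly new) stack:
#' `Vhat = sum a_m W_m + sum_{m<=n} b_mn R_mn + c (u u^T - I)` with the
#' symmetrized quadratic regressors of [build_terms()].  The diagonal is
#' fixed at zero (the zeroth-order term only offsets the unmodelled
#' diagonal).  Predicted entries are not clipped to `[-1, 1]`.
#'
#' @param object A `taylor_fit`.
#' @param stack A [matrix_stack] compatible with the fit's spec.
#' @param ... Unused.
#' @return A [connectivity_matrix] (metric `"generic"`).
#' @export
predict.taylor_fit <- function(object, stack, ...) {
  terms <- build_terms(stack, object$spec)
  if (!identical(colnames(terms$design), object$term_names)) {
    stop("predict.taylor_fit: stack terms do not match the fitted terms")
  }
  yhat <- drop(terms$design %*% object$coefficients)
  vhat <- sym_from_upper(yhat, length(terms$region_labels),
                         terms$region_labels)
  connectivity_matrix(vhat, metric = "generic",
                      region_labels = terms$region_labels,
                      symmetrize_tol = 1e-9)
}

#' Coefficient of determination over unique off-diagonal elements
#'
#' `1 - SSE/SST` with SST about the mean of the target's elements,
#' computed on the E = P(P-1)/2 upper-triangle off-diagonal entries.
#'
#' @param V Target matrix.
#' @param Vhat Predicted matrix with the same labels.
#' @return Scalar (at most 1; negative when the prediction is worse than
#'   the mean).
#' @export
r_squared <- function(V, Vhat) {
  v <- upper_tri_vec(V); vh <- upper_tri_vec(Vhat)
  stopifnot(length(v) == length(vh))
  sst <- sum((v - mean(v))^2)
  if (sst == 0) stop("r_squared: constant target, R^2 undefined")
  1 - sum((v - vh)^2) / sst
}

#' Spectral diagnostics of a matrix stack
#'
#' Eigenvalues, spectral radius and trace per matrix.  The expansion
#' about zero converges when the spectral radius stays below the
#' (unknown) radius of convergence; since every matrix has zero trace
#' the eigenvalues are centred on zero, and a spectral radius >= 1
#' triggers a warning as the standard heuristic reference point.
#'
#' @param stack A [matrix_stack].
#' @return Data frame with one row per matrix: `name`, `trace`,
#'   `lambda_max` (largest modulus), plus list-column `eigenvalues`.
#' @export
spectral_check <- function(stack) {
  stopifnot(inherits(stack, "matrix_stack"))
  res <- lapply(names(stack$matrices), function(nm) {
    w <- unclass_cm(stack$matrices[[nm]])
    ev <- eigen(w, symmetric = TRUE, only.values = TRUE)$values
    list(name = nm, trace = sum(diag(w)), lambda_max = max(abs(ev)),
         eigenvalues = ev)
  })
  out <- data.frame(
    name = vapply(res, `[[`, character(1), "name"),
    trace = vapply(res, `[[`, numeric(1), "trace"),
    lambda_max = vapply(res, `[[`, numeric(1), "lambda_max"),
    stringsAsFactors = FALSE
  )
  out$eigenvalues <- lapply(res, `[[`, "eigenvalues")
  if (any(out$lambda_max >= 1)) {
    warning("spectral_check: spectral radius >= 1 for: ",
            paste(out$name[out$lambda_max >= 1], collapse = ", "))
  }
  out
}

#' Fit an ordered sequence of nested models
#'
#' Fits each spec in turn and checks that the regressor sets are nested
#' (each model's terms contain the previous model's); for a nested
#' sequence the R^2 values are necessarily non-decreasing and this is
#' asserted numerically.  A non-nested sequence is fitted with a warning
#' and no monotonicity assertion.
#'
#' @param V Target [connectivity_matrix].
#' @param stack A [matrix_stack].
#' @param variants Ordered list of [model_spec] objects.
#' @return List of `taylor_fit` objects, named by variant.
#' @export
fit_model_sequence <- function(V, stack, variants) {
  stopifnot(length(variants) >= 1)
  fits <- vector("list", length(variants))
  names(fits) <- vapply(variants, `[[`, character(1), "variant")
  prev_terms <- character(0)
  nested <- TRUE
  for (i in seq_along(variants)) {
    tl <- build_terms(stack, variants[[i]])
    if (!all(prev_terms %in% colnames(tl$design))) nested <- FALSE
    prev_terms <- colnames(tl$design)
    fits[[i]] <- fit_taylor(V, tl)
  }
  r2s <- vapply(fits, `[[`, numeric(1), "r2")
  if (!nested) {
    warning("fit_model_sequence: variants are not nested; ",
            "R^2 monotonicity not guaranteed")
  } else if (any(diff(r2s) < -1e-10)) {
    stop("fit_model_sequence: R^2 decreased along a nested sequence ",
         "(numerical failure): ", paste(signif(r2s, 6), collapse = ", "))
  }
  fits
}

#' The standard nested variant sequence
#'
#' Best-single-frequency, linear, nonlinear, nonlinear-with-cross-terms
#' for one metric.  The single-frequency entry is chosen as the single
#' input matrix with maximal R^2 on the given target ("only the best
#' single frequency enters the sequence").
#'
#' @param V Target matrix.
#' @param stack A [matrix_stack].
#' @param metric Metric to restrict to (for mixed stacks), or `NULL`.
#' @return List of four [model_spec] objects (attribute `best_single`
#'   names the winning matrix).
#' @export
nested_variants <- function(V, stack, metric = NULL) {
  idx <- stack$index
  keep <- if (is.null(metric)) rep(TRUE, nrow(idx))
          else toupper(idx$metric) == toupper(metric)
  if (!any(keep)) stop("nested_variants: no matrices for metric ", metric)
  nms <- idx$name[keep]
  metrics <- if (is.null(metric)) NULL else metric
  r2b <- vapply(nms, function(nm) {
    fit_taylor(V, stack,
               model_spec("single_frequency", matrices = nm))$r2
  }, numeric(1))
  best <- nms[which.max(r2b)]
  out <- list(
    model_spec("single_frequency", matrices = best),
    model_spec("linear", metrics = metrics, matrices = nms),
    model_spec("nonlinear", metrics = metrics, matrices = nms),
    model_spec("nonlinear_cross", metrics = metrics, matrices = nms)
  )
  attr(out, "best_single") <- best
  out
}
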