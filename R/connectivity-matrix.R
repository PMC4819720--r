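#' Construct a validated connectivity matrix
#'
#' A `connectivity_matrix` is a P x P symmetric weighted adjacency matrix
#' with an exactly-zero diagonal, holding one functional-connectivity
#' estimate per region pair for a given metric and (optionally) frequency
#' band.  PLI entries lie in `[0, 1]`; AEC and Pearson entries in
#' `[-1, 1]`.  The zero diagonal implies zero trace, the property the
#' Taylor-expansion convergence argument relies on.
#'
#' @param weights Square numeric matrix.
#' @param metric One of `"PLI"`, `"AEC"`, `"Pearson"`, or `"generic"` for
#'   matrices (e.g. model predictions, surrogates) not tied to a metric's
#'   range constraint.
#' @param band Optional [frequency_band].
#' @param region_labels Character vector of region names; defaults to the
#'   matrix dimnames or `R1..RP`.
#' @param symmetrize_tol Maximum allowed asymmetry `max|W - t(W)|`;
#'   asymmetry within tolerance is removed by averaging, beyond it is an
#'   error.
#' @return An object of class `connectivity_matrix` (a matrix with
#'   attributes `metric`, `band`).
#' @export
connectivity_matrix <- function(weights, metric = "generic", band = NULL,
                                region_labels = NULL,
                                symmetrize_tol = 1e-12) {
  weights <- as.matrix(weights)
  if (nrow(weights) != ncol(weights)) {
    stop("connectivity_matrix: weights must be square, got ",
         nrow(weights), " x ", ncol(weights))
  }
  if (anyNA(weights) || !all(is.finite(weights))) {
    stop("connectivity_matrix: weights contain missing/non-finite values")
  }
  P <- nrow(weights)
  if (P < 2) stop("connectivity_matrix: need at least 2 regions")
  asym <- max(abs(weights - t(weights)))
  if (asym > symmetrize_tol) {
    stop("connectivity_matrix: asymmetry ", format(asym),
         " exceeds tolerance ", format(symmetrize_tol))
  }
  weights <- (weights + t(weights)) / 2
  if (any(diag(weights) != 0)) {
    if (max(abs(diag(weights))) > symmetrize_tol) {
      warning("connectivity_matrix: nonzero diagonal forced to zero ",
              "(max |diag| = ", format(max(abs(diag(weights)))), ")")
    }
    diag(weights) <- 0
  }
  metric <- match.arg(metric, c("PLI", "AEC", "Pearson", "generic"))
  rng <- range(weights)
  if (metric == "PLI" && (rng[1] < 0 || rng[2] > 1)) {
    stop("connectivity_matrix: PLI entries must lie in [0, 1]")
  }
  if (metric %in% c("AEC", "Pearson") && (rng[1] < -1 || rng[2] > 1)) {
    stop("connectivity_matrix: ", metric, " entries must lie in [-1, 1]")
  }
  if (is.null(region_labels)) {
    region_labels <- rownames(weights) %||% paste0("R", seq_len(P))
  }
  if (length(region_labels) != P) {
    stop("connectivity_matrix: ", length(region_labels),
         " labels for ", P, " regions")
  }
  dimnames(weights) <- list(region_labels, region_labels)
  structure(weights, metric = metric, band = band,
            class = c("connectivity_matrix", "matrix", "array"))
}

#' Test for the connectivity_matrix class
#' @param x Object.
#' @return Logical.
#' @export
is_connectivity_matrix <- function(x) inherits(x, "connectivity_matrix")

#' @export
print.connectivity_matrix <- function(x, ...) {
  b <- attr(x, "band")
  cat(sprintf("<connectivity_matrix> %d x %d, metric = %s%s\n",
              nrow(x), ncol(x), attr(x, "metric"),
              if (!is.null(b)) paste0(", band = ", b$name) else ""))
  print(unclass_cm(x)[seq_len(min(6L, nrow(x))), seq_len(min(6L, ncol(x)))])
  if (nrow(x) > 6) cat("... (", nrow(x), " regions)\n", sep = "")
  invisible(x)
}

#' Strip connectivity_matrix attributes, returning a plain matrix
#' @param x A `connectivity_matrix`.
#' @return A base matrix.
#' @keywords internal
unclass_cm <- function(x) {
  attr(x, "metric") <- NULL
  attr(x, "band") <- NULL
  class(x) <- NULL
  x
}

#' Region labels of a connectivity matrix or stack
#' @param x A `connectivity_matrix` or `matrix_stack`.
#' @return Character vector.
#' @export
region_labels <- function(x) {
  if (inherits(x, "matrix_stack")) return(x$region_labels)
  rownames(x)
}

#' Vectorize the upper-triangle off-diagonal entries
#'
#' Extracts the E = P(P-1)/2 unique off-diagonal elements (column-major
#' upper triangle), the data vector that all model fitting operates on.
#'
#' @param w Square matrix.
#' @return Numeric vector of length `P(P-1)/2`.
#' @export
upper_tri_vec <- function(w) {
  w <- as.matrix(w)
  w[upper.tri(w)]
}

#' Rebuild a symmetric zero-diagonal matrix from its upper triangle
#'
#' Inverse of [upper_tri_vec()].
#'
#' @param v Vector of length `P(P-1)/2`.
#' @param P Number of regions.
#' @param labels Optional region labels.
#' @return P x P symmetric matrix with zero diagonal.
#' @export
sym_from_upper <- function(v, P, labels = NULL) {
  stopifnot(length(v) == P * (P - 1) / 2)
  m <- matrix(0, P, P)
  m[upper.tri(m)] <- v
  m <- m + t(m)
  if (!is.null(labels)) dimnames(m) <- list(labels, labels)
  m
}
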