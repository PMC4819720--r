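#' Group connectivity matrices into an ordered stack
#'
#' A `matrix_stack` is the ordered collection `W = (W_1, ..., W_D)` of
#' connectivity matrices sharing one region set, the multivariate input
#' of the Taylor expansion.  Each element is indexed by a name encoding
#' its (metric, band) pair.
#'
#' @param matrices Named list of [connectivity_matrix] objects with
#'   identical region labels.  Unnamed lists get names `W1..WD`.
#' @return An object of class `matrix_stack` with fields `matrices`,
#'   `region_labels`, `index` (data.frame of name, metric, band per
#'   matrix).
#' @export
matrix_stack <- function(matrices) {
  if (!is.list(matrices) || length(matrices) < 1) {
    stop("matrix_stack: need a non-empty list of connectivity matrices")
  }
  ok <- vapply(matrices, is_connectivity_matrix, logical(1))
  if (!all(ok)) stop("matrix_stack: elements ",
                     paste(which(!ok), collapse = ", "),
                     " are not connectivity matrices")
  labels <- region_labels(matrices[[1]])
  same <- vapply(matrices, function(m) identical(region_labels(m), labels),
                 logical(1))
  if (!all(same)) stop("matrix_stack: region labels differ across matrices")
  if (is.null(names(matrices)) || any(names(matrices) == "")) {
    names(matrices) <- paste0("W", seq_along(matrices))
  }
  index <- data.frame(
    name = names(matrices),
    metric = vapply(matrices, function(m) attr(m, "metric"), character(1)),
    band = vapply(matrices, function(m) {
      b <- attr(m, "band"); if (is.null(b)) NA_character_ else b$name
    }, character(1)),
    stringsAsFactors = FALSE
  )
  rownames(index) <- NULL
  structure(list(matrices = matrices, region_labels = labels,
                 index = index),
            class = "matrix_stack")
}

#' @export
print.matrix_stack <- function(x, ...) {
  cat(sprintf("<matrix_stack> D = %d matrices, P = %d regions\n",
              length(x$matrices), length(x$region_labels)))
  print(x$index)
  invisible(x)
}

#' @export
length.matrix_stack <- function(x) length(x$matrices)

#' Select a subset of a matrix stack
#'
#' @param stack A [matrix_stack].
#' @param names Names of matrices to keep (order preserved as given).
#' @return A [matrix_stack].
#' @export
stack_subset <- function(stack, names) {
  stopifnot(inherits(stack, "matrix_stack"))
  missing <- setdiff(names, names(stack$matrices))
  if (length(missing)) {
    stop("stack_subset: unknown matrices: ",
         paste(missing, collapse = ", "))
  }
  matrix_stack(stack$matrices[names])
}
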