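#' Write a connectivity matrix as labelled TSV
#'
#' Tab-delimited text, label header row, label first column.  Values are
#' written with 17 significant digits so read/write round trips are
#' exact in double precision.  Metric and band are recorded in a JSON
#' sidecar `<path>.meta.json`.
#'
#' @param W A [connectivity_matrix].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(W, path) {
  stopifnot(is_connectivity_matrix(W))
  m <- unclass_cm(W)
  df <- data.frame(region = rownames(m),
                   format(m, digits = 17, scientific = TRUE,
                          trim = TRUE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  b <- attr(W, "band")
  meta <- list(metric = attr(W, "metric"),
               band = if (is.null(b)) NULL else
                 list(name = b$name, low = b$low, high = b$high))
  jsonlite::write_json(meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a connectivity matrix from labelled TSV
#'
#' Expects the format written by [write_matrix()]: header row of region
#' labels, first column of region labels, square numeric body.  Row and
#' column labels must agree; asymmetry within `1e-12` is removed by
#' averaging (round-trip float noise), beyond it is an error; a nonzero
#' diagonal is forced to zero with a warning.  The metric/band sidecar
#' is honoured when present.
#'
#' @param path File path.
#' @return A [connectivity_matrix].
#' @export
read_matrix <- function(path) {
  if (!file.exists(path)) stop("read_matrix: no such file: ", path)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, colClasses = "character")
  labels <- df[[1]]
  body <- df[, -1, drop = FALSE]
  if (nrow(body) != ncol(body)) {
    stop("read_matrix: non-square body (", nrow(body), " x ",
         ncol(body), ") in ", path)
  }
  if (!identical(labels, colnames(body))) {
    stop("read_matrix: row/column label mismatch in ", path)
  }
  suppressWarnings(num <- vapply(body, as.numeric, numeric(nrow(body))))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1, ]
    stop("read_matrix: non-numeric cell at row '", labels[bad[1]],
         "', column '", colnames(body)[bad[2]], "' in ", path)
  }
  num <- matrix(num, nrow(body), dimnames = list(labels, labels))
  metric <- "generic"; band <- NULL
  meta_path <- paste0(path, ".meta.json")
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path)
    metric <- meta$metric %||% "generic"
    if (!is.null(meta$band$name)) {
      band <- frequency_band(meta$band$name, meta$band$low,
                             meta$band$high)
    }
  }
  connectivity_matrix(num, metric = metric, band = band,
                      region_labels = labels)
}

#' Write regional time series as TSV plus metadata sidecar
#'
#' Rows are regions (label first column); the sidecar
#' `<path>.meta.json` carries the sampling rate, modality and band.
#'
#' @param ts A [regional_ts].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(ts, path) {
  stopifnot(inherits(ts, "regional_ts"))
  df <- data.frame(region = ts$region_labels,
                   format(ts$data, digits = 17, scientific = TRUE,
                          trim = TRUE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  b <- ts$band
  meta <- list(sampling_rate = ts$sampling_rate,
               modality = ts$modality,
               band = if (is.null(b)) NULL else
                 list(name = b$name, low = b$low, high = b$high))
  jsonlite::write_json(meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read regional time series written by [write_timeseries()]
#'
#' @param path TSV file path.
#' @param meta_path Sidecar path; default `<path>.meta.json`.  The
#'   sidecar must exist and carry `sampling_rate`.
#' @return A [regional_ts].
#' @export
read_timeseries <- function(path, meta_path = paste0(path, ".meta.json")) {
  if (!file.exists(path)) stop("read_timeseries: no such file: ", path)
  if (!file.exists(meta_path)) {
    stop("read_timeseries: missing metadata sidecar: ", meta_path)
  }
  meta <- jsonlite::read_json(meta_path)
  if (is.null(meta$sampling_rate)) {
    stop("read_timeseries: sidecar lacks sampling_rate")
  }
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  labels <- df[[1]]
  data <- as.matrix(df[, -1, drop = FALSE])
  if (anyNA(data)) stop("read_timeseries: NaN/missing cells in ", path)
  dimnames(data) <- list(labels, NULL)
  band <- NULL
  if (!is.null(meta$band$name)) {
    band <- frequency_band(meta$band$name, meta$band$low, meta$band$high)
  }
  regional_ts(data, meta$sampling_rate, labels, band = band,
              modality = meta$modality %||% "electrophysiological")
}

#' Serialize a taylor_fit to a JSON report plus matrix files
#'
#' @param fit A `taylor_fit`.
#' @param dir Output directory (created if absent).
#' @param name Base name for the files.
#' @return The JSON path, invisibly.
#' @export
write_fit <- function(fit, dir, name = "fit") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ci <- fit$ci
  report <- list(
    variant = fit$spec$variant,
    r2 = fit$r2,
    coefficients = as.list(fit$coefficients),
    ci = list(lower = as.list(stats::setNames(ci[, 1], rownames(ci))),
              upper = as.list(stats::setNames(ci[, 2], rownames(ci)))),
    sigma = fit$sigma,
    rank_deficient = fit$rank_deficient,
    out_of_range = fit$out_of_range
  )
  jp <- file.path(dir, paste0(name, ".json"))
  jsonlite::write_json(report, jp, auto_unbox = TRUE, digits = NA)
  write_matrix(connectivity_matrix(fit$fitted, region_labels =
                                     rownames(fit$fitted),
                                   symmetrize_tol = 1e-9),
               file.path(dir, paste0(name, "_fitted.tsv")))
  write_matrix(connectivity_matrix(fit$residual, region_labels =
                                     rownames(fit$residual),
                                   symmetrize_tol = 1e-9),
               file.path(dir, paste0(name, "_residual.tsv")))
  invisible(jp)
}

#' Run the full synthetic or file-driven analysis pipeline
#'
#' Orchestrates connectivity-stack construction (or loading), the
#' nested model sequence, the three permutation tests and the per-band
#' regional contributions, writing all artifacts plus a single summary
#' JSON under `out_dir`.  With `target` and `stack` given the
#' connectivity stage is skipped.
#'
#' @param target A [connectivity_matrix] (the haemodynamic matrix), or
#'   path to one.
#' @param stack A [matrix_stack], or directory of TSV matrices.
#' @param metric Optional metric restriction for the model sequence.
#' @param n_perm Permutations per test.
#' @param seed Master seed (logged; all randomness derives from it).
#' @param out_dir Output directory.
#' @return The summary list, invisibly; artifacts on disk.
#' @export
run_pipeline <- function(target, stack, metric = NULL, n_perm = 200,
                         seed = 1, out_dir = tempfile("taylorconn_")) {
  if (is.character(target)) target <- read_matrix(target)
  if (is.character(stack)) {
    files <- sort(list.files(stack, pattern = "\\.tsv$",
                             full.names = TRUE))
    files <- files[!grepl("meta", files)]
    mats <- lapply(files, read_matrix)
    names(mats) <- sub("\\.tsv$", "", basename(files))
    stack <- matrix_stack(mats)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  variants <- nested_variants(target, stack, metric = metric)
  fits <- fit_model_sequence(target, stack, variants)
  for (nm in names(fits)) write_fit(fits[[nm]], out_dir, nm)
  t1 <- test_variance_explained(target, stack, variants[[4]],
                                n_perm = n_perm,
                                seed = child_seed(seed, 11))
  t2a <- test_gradient(target, stack, variants, n_perm = n_perm,
                       seed = child_seed(seed, 12))
  t2b <- test_increments(target, stack, variants, n_perm = n_perm,
                         seed = child_seed(seed, 13))
  contrib <- lapply(stack$index$name, function(nm) {
    tryCatch(regional_contribution(target, stack, matrix_name = nm),
             warning = function(w) NULL)
  })
  names(contrib) <- stack$index$name
  summ <- list(
    seed = seed, n_perm = n_perm,
    best_single = attr(variants, "best_single"),
    r2 = lapply(fits, `[[`, "r2"),
    test1 = list(observed = t1$observed, p = t1$p_value,
                 bonferroni_alpha = t1$bonferroni_alpha,
                 significant = t1$significant),
    test2a = list(slope = t2a$observed, p = t2a$p_value,
                  r2_sequence = t2a$observed_r2),
    test2b = lapply(t2b, function(r) {
      list(delta_r2 = r$observed, p = r$p_value,
           significant = r$significant)
    }),
    regional = lapply(contrib, function(rc) {
      if (is.null(rc)) NULL
      else list(r2 = rc$r2, n_retained = rc$n_retained)
    })
  )
  jsonlite::write_json(summ, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(summ)
}
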