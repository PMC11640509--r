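fmt_num <- function(x) sprintf("%.17g", x)

#' Write a spectra set as delimited text
#'
#' Comma-separated: first column `sample_id`, remaining headers the
#' wavenumbers in cm-1 (ascending), values written at full precision (17
#' significant digits) so that [read_spectra()] round-trips exactly.
#'
#' @param s A [spectra_set()].
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_spectra <- function(s, path) {
  stopifnot(inherits(s, "spectra_set"))
  if (nrow(s$absorbance) < 1L) stopf("empty sample set")
  header <- paste(c("sample_id", fmt_num(s$wavenumbers)), collapse = ",")
  rows <- vapply(seq_len(nrow(s$absorbance)), function(i) {
    paste(c(s$sample_ids[i], fmt_num(s$absorbance[i, ])), collapse = ",")
  }, character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read a spectra set from delimited text
#'
#' Inverse of [write_spectra()]. Rejects malformed input (ragged rows,
#' non-numeric cells, duplicate wavenumbers) rather than coercing; columns
#' are reordered ascending with a warning when needed.
#'
#' @param path File written by [write_spectra()] (or matching its layout).
#' @return A [spectra_set()].
#' @export
read_spectra <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path)
  if (length(lines) < 2L) stopf("spectra file has no samples")
  header <- strsplit(lines[1], ",", fixed = TRUE)[[1]]
  if (header[1] != "sample_id") stopf("first column must be sample_id")
  wn <- suppressWarnings(as.numeric(header[-1]))
  if (anyNA(wn)) stopf("non-numeric wavenumber in header: %s",
                       header[-1][which(is.na(wn))[1]])
  p <- length(wn)
  body <- strsplit(lines[-1], ",", fixed = TRUE)
  len <- lengths(body)
  if (any(len != p + 1L))
    stopf("ragged row %d: expected %d fields, found %d",
          which(len != p + 1L)[1] + 1L, p + 1L, len[len != p + 1L][1])
  ids <- vapply(body, `[[`, character(1), 1L)
  vals <- suppressWarnings(
    vapply(body, function(r) as.numeric(r[-1]), numeric(p)))
  X <- if (p == 1L) matrix(vals, ncol = 1L) else t(vals)
  if (anyNA(X)) {
    bad <- which(is.na(X), arr.ind = TRUE)[1, ]
    stopf("non-numeric value at row %d, wavenumber %g", bad[1], wn[bad[2]])
  }
  spectra_set(X, wn, ids)
}

#' Write / read a quality table
#'
#' Comma-separated with the fixed schema `sample_id, ssc, ta, L, a, b, C, h,
#' Fp, Ff, spi, daf`. Reading validates the physical invariants (positive
#' SSC and SPI, hue in `[0, 360)`, non-negative hardness and chroma) and
#' errors on missing columns by name.
#'
#' @param q A quality table.
#' @param path File path.
#' @return `write_quality`: the path, invisibly. `read_quality`: a validated
#'   `quality_table`.
#' @export
write_quality <- function(q, path) {
  validate_quality(q)
  cols <- c("sample_id", quality_columns(), "daf")
  header <- paste(cols, collapse = ",")
  rows <- vapply(seq_len(nrow(q)), function(i) {
    paste(c(q$sample_id[i],
            fmt_num(unlist(q[i, c(quality_columns(), "daf")]))), collapse = ",")
  }, character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' @rdname write_quality
#' @export
read_quality <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  for (col in c("sample_id", quality_columns(), "daf"))
    if (!col %in% names(df)) stopf("missing column %s", col)
  validate_quality(df)
  class(df) <- c("quality_table", "data.frame")
  df
}

#' Write / read a post-ripening table
#'
#' @param x A [simulate_postripening()] table.
#' @param path File path.
#' @return `write_postripening`: the path, invisibly. `read_postripening`:
#'   the validated table.
#' @export
write_postripening <- function(x, path) {
  cols <- c("daf", "a", "ssc", "ta", "edible_rate", "rot_rate")
  if (!all(cols %in% names(x))) stopf("missing column %s", setdiff(cols, names(x))[1])
  header <- paste(cols, collapse = ",")
  rows <- vapply(seq_len(nrow(x)), function(i)
    paste(fmt_num(unlist(x[i, cols])), collapse = ","), character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' @rdname write_postripening
#' @export
read_postripening <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  for (col in c("daf", "a", "ssc", "ta", "edible_rate", "rot_rate"))
    if (!col %in% names(df)) stopf("missing column %s", col)
  rates <- c(df$edible_rate, df$rot_rate)
  if (any(rates < 0 | rates > 100)) stopf("rates must lie in [0, 100]")
  class(df) <- c("postripening_table", "data.frame")
  df
}

MODEL_SCHEMA_VERSION <- 1L

#' Persist a fitted PLS model as structured text
#'
#' JSON with an explicit `schema_version`; stores the preprocessing name,
#' selected variable indices and wavenumbers, centering means, per-size
#' coefficient matrix and intercepts, so a reloaded model predicts
#' identically.
#'
#' @param model A [pls_fit()] model.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "pls_model"))
  payload <- list(
    schema_version = MODEL_SCHEMA_VERSION,
    type = "pls_model",
    preprocess = model$preprocess,
    selected = model$selected,
    selected_wavenumbers = model$selected_wavenumbers,
    n_components = model$n_components,
    x_mean = model$x_mean, y_mean = model$y_mean, x_scale = model$x_scale,
    weights = model$weights, x_loadings = model$x_loadings,
    y_loadings = model$y_loadings,
    coefficients = model$coefficients, intercepts = model$intercepts,
    msc_reference = model$msc_reference
  )
  writeLines(jsonlite::toJSON(payload, digits = NA, auto_unbox = TRUE,
                              null = "null", matrix = "columnmajor"), path)
  invisible(path)
}

#' Load a persisted PLS model
#'
#' @param path File written by [save_model()].
#' @return A `pls_model`.
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  obj <- jsonlite::fromJSON(readLines(path))
  if (is.null(obj$schema_version) || obj$schema_version != MODEL_SCHEMA_VERSION)
    stopf("model schema version mismatch: found %s, expected %d",
          obj$schema_version %||% "none", MODEL_SCHEMA_VERSION)
  if (!identical(obj$type, "pls_model")) stopf("not a pls_model file")
  p <- length(obj$x_mean); A <- obj$n_components
  # column-major JSON arrays parse as one row per stored column: transpose back
  as_mat <- function(m) {
    out <- if (is.matrix(m)) t(m) else matrix(as.numeric(unlist(m)), p, A)
    if (!all(dim(out) == c(p, A))) stopf("malformed model matrix block")
    out
  }
  structure(list(
    x_mean = as.numeric(obj$x_mean), y_mean = obj$y_mean,
    x_scale = as.numeric(obj$x_scale),
    weights = as_mat(obj$weights), x_loadings = as_mat(obj$x_loadings),
    y_loadings = as.numeric(obj$y_loadings),
    coefficients = as_mat(obj$coefficients),
    intercepts = as.numeric(obj$intercepts),
    n_components = A,
    selected = if (is.null(obj$selected)) NULL else as.integer(obj$selected),
    selected_wavenumbers = obj$selected_wavenumbers,
    preprocess = obj$preprocess,
    msc_reference = if (is.null(obj$msc_reference)) NULL
                    else as.numeric(obj$msc_reference)
  ), class = "pls_model")
}
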