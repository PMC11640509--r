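#' Construct a spectra set
#'
#' Container for a sample-by-wavenumber absorbance matrix with its wavenumber
#' axis (cm-1) and sample identifiers. Wavenumbers are stored strictly
#' ascending; columns supplied in another order are sorted (with a warning).
#'
#' @param absorbance Numeric matrix, one row per sample.
#' @param wavenumbers Numeric vector of unique wavenumbers in cm-1.
#' @param sample_ids Character vector of sample identifiers (default `S1..Sn`).
#' @return An object of class `spectra_set` with elements `absorbance`
#'   (matrix with sample ids as rownames), `wavenumbers` and `sample_ids`.
#' @export
spectra_set <- function(absorbance, wavenumbers, sample_ids = NULL) {
  absorbance <- as.matrix(absorbance)
  if (!is.numeric(absorbance)) stopf("absorbance must be numeric")
  if (nrow(absorbance) < 1L) stopf("spectra set must contain at least one sample")
  if (anyNA(absorbance)) stopf("absorbance matrix contains missing values")
  wavenumbers <- as.numeric(wavenumbers)
  if (length(wavenumbers) != ncol(absorbance))
    stopf("length of wavenumbers (%d) does not match number of columns (%d)",
          length(wavenumbers), ncol(absorbance))
  if (anyDuplicated(wavenumbers)) {
    dup <- wavenumbers[duplicated(wavenumbers)][1]
    stopf("duplicated wavenumber: %g cm-1", dup)
  }
  if (is.unsorted(wavenumbers)) {
    warnf("wavenumbers not ascending; reordering columns")
    o <- order(wavenumbers)
    wavenumbers <- wavenumbers[o]
    absorbance <- absorbance[, o, drop = FALSE]
  }
  sample_ids <- as.character(sample_ids %||% paste0("S", seq_len(nrow(absorbance))))
  if (length(sample_ids) != nrow(absorbance))
    stopf("length of sample_ids does not match number of rows")
  if (anyDuplicated(sample_ids)) stopf("sample_ids must be unique")
  dimnames(absorbance) <- list(sample_ids, NULL)
  structure(list(absorbance = absorbance, wavenumbers = wavenumbers,
                 sample_ids = sample_ids),
            class = "spectra_set")
}

#' @export
print.spectra_set <- function(x, ...) {
  cat(sprintf("Spectra set: %d samples x %d points (%g-%g cm-1)\n",
              nrow(x$absorbance), length(x$wavenumbers),
              min(x$wavenumbers), max(x$wavenumbers)))
  invisible(x)
}

#' @export
dim.spectra_set <- function(x) dim(x$absorbance)

#' Subset a spectra set by sample and/or wavenumber position
#' @param x A `spectra_set`.
#' @param i Sample index (integer, logical or sample id).
#' @param j Wavenumber position index.
#' @param ... Unused.
#' @return A `spectra_set`.
#' @export
`[.spectra_set` <- function(x, i, j, ...) {
  a <- x$absorbance
  if (missing(i)) i <- seq_len(nrow(a))
  if (missing(j)) j <- seq_along(x$wavenumbers)
  spectra_set(a[i, j, drop = FALSE], x$wavenumbers[j], x$sample_ids[i])
}

quality_columns <- function() c("ssc", "ta", "L", "a", "b", "C", "h", "Fp", "Ff", "spi")

# Validate a quality table against the schema and physical invariants.
validate_quality <- function(q) {
  if (!is.data.frame(q)) stopf("quality table must be a data frame")
  for (col in c(quality_columns(), "daf")) {
    if (!col %in% names(q)) stopf("missing column %s", col)
    if (!is.numeric(q[[col]])) stopf("column %s must be numeric", col)
    if (anyNA(q[[col]])) stopf("column %s contains missing values", col)
  }
  if (any(q$ssc <= 0)) stopf("ssc must be positive")
  if (any(q$Fp < 0) || any(q$Ff < 0)) stopf("Fp and Ff must be non-negative")
  if (any(q$h < 0 | q$h >= 360)) stopf("h (hue angle) must lie in [0, 360)")
  if (any(q$C < 0)) stopf("C (chroma) must be non-negative")
  if (any(q$spi <= 0)) stopf("spi must be positive")
  invisible(q)
}
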