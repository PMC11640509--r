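as_absorbance <- function(s) {
  if (inherits(s, "spectra_set")) s$absorbance else as.matrix(s)
}

rewrap <- function(s, X) {
  if (inherits(s, "spectra_set")) { s$absorbance <- X; s } else X
}

#' Standard normal variate (SNV) transformation
#'
#' Standardizes each spectrum to zero mean and unit standard deviation
#' (denominator `n - 1`), removing additive offsets and multiplicative
#' scatter per sample.
#'
#' @param s A [spectra_set()] or numeric matrix (one spectrum per row).
#' @return Object of the same type as `s`.
#' @export
snv <- function(s) {
  X <- as_absorbance(s)
  sds <- apply(X, 1, sd)
  if (any(sds == 0)) {
    bad <- rownames(X)[which(sds == 0)[1]] %||% which(sds == 0)[1]
    stopf("constant spectrum (sample %s): SNV undefined", bad)
  }
  rewrap(s, (X - rowMeans(X)) / sds)
}

#' Multiplicative scatter correction (MSC)
#'
#' Regresses each spectrum on a reference spectrum, `x ~ a + b * ref`, by
#' least squares and returns the corrected spectrum `(x - a)/b`. The default
#' reference is the mean spectrum of the set; pass the calibration-set
#' reference when correcting new spectra (it is frozen into fitted models to
#' avoid leakage).
#'
#' @param s A [spectra_set()] or numeric matrix.
#' @param reference Reference spectrum; default mean of `s`.
#' @return Same type as `s`, with the reference stored in attribute
#'   `msc_reference`.
#' @export
msc <- function(s, reference = NULL) {
  X <- as_absorbance(s)
  if (is.null(reference)) {
    if (nrow(X) < 2L) stopf("MSC with mean reference needs at least 2 spectra")
    reference <- colMeans(X)
  }
  if (length(reference) != ncol(X))
    stopf("reference length (%d) does not match spectrum length (%d)",
          length(reference), ncol(X))
  rc <- reference - mean(reference)
  denom <- sum(rc^2)
  b <- as.vector(X %*% rc) / denom
  if (any(abs(b) < 1e-10)) {
    bad <- rownames(X)[which(abs(b) < 1e-10)[1]] %||% which(abs(b) < 1e-10)[1]
    stopf("MSC slope ~ 0 for sample %s", bad)
  }
  a <- rowMeans(X) - b * mean(reference)
  out <- rewrap(s, (X - a) / b)
  attr(out, "msc_reference") <- reference
  out
}

#' Savitzky-Golay smoothing / derivative filter
#'
#' Local polynomial least-squares filtering along the wavenumber axis.
#' Derivatives are scaled by the axis step (units: absorbance per cm-1 for
#' `deriv = 1`, per cm-2 for `deriv = 2`); edges are handled by one-sided
#' polynomial fits.
#'
#' @param s A [spectra_set()] or numeric matrix.
#' @param window Odd window length, greater than `polyorder`.
#' @param polyorder Polynomial order (must be >= `deriv`).
#' @param deriv Derivative order: 0 (smoothing), 1 or 2.
#' @param step Axis step used to scale derivatives. Defaults to the
#'   wavenumber spacing of a `spectra_set`, or 1 for a bare matrix.
#' @return Same type as `s`.
#' @export
sg_filter <- function(s, window = 15, polyorder = 2, deriv = 0, step = NULL) {
  window <- assert_count(window, "window", min = 3L)
  polyorder <- assert_count(polyorder, "polyorder", min = 0L)
  deriv <- assert_count(deriv, "deriv", min = 0L)
  if (window %% 2L == 0L) stopf("window must be odd")
  if (window <= polyorder) stopf("window must exceed polyorder")
  if (deriv > polyorder) stopf("deriv must not exceed polyorder")
  if (deriv > 2L) stopf("deriv must be 0, 1 or 2")
  X <- as_absorbance(s)
  if (ncol(X) < window) stopf("spectra have fewer points (%d) than the window (%d)",
                              ncol(X), window)
  if (is.null(step)) {
    step <- if (inherits(s, "spectra_set")) mean(diff(s$wavenumbers)) else 1
  }
  out <- t(apply(X, 1, signal::sgolayfilt, p = polyorder, n = window,
                 m = deriv, ts = step))
  rewrap(s, out)
}

#' Preprocessing specification
#'
#' One of the five pretreatments: `"sg"` (Savitzky-Golay smoothing), `"snv"`,
#' `"msc"`, `"snv1d"` (SNV then first SG derivative) or `"msc2d"` (MSC then
#' second SG derivative). Scatter correction is always applied before the
#' derivative.
#'
#' @param method Method name.
#' @param sg_window SG window length (odd).
#' @param sg_polyorder SG polynomial order; default 2, or 3 for the second
#'   derivative.
#' @return An object of class `preprocess_spec`.
#' @export
preprocess_spec <- function(method = c("sg", "snv", "msc", "snv1d", "msc2d"),
                            sg_window = 15,
                            sg_polyorder = NULL) {
  method <- match.arg(method)
  deriv <- switch(method, snv1d = 1L, msc2d = 2L, sg = 0L, 0L)
  sg_polyorder <- sg_polyorder %||% if (deriv == 2L) 3L else 2L
  if (sg_window %% 2L == 0L || sg_window <= sg_polyorder)
    stopf("sg_window must be odd and exceed sg_polyorder")
  structure(list(method = method, sg_window = sg_window,
                 sg_polyorder = sg_polyorder, deriv = deriv),
            class = "preprocess_spec")
}

#' Apply a preprocessing specification
#'
#' @param spec A [preprocess_spec()] (or a method name).
#' @param s A [spectra_set()] or matrix.
#' @param reference MSC reference spectrum; default mean of `s`. Ignored for
#'   non-MSC methods.
#' @return Same type as `s`; for MSC methods the fitted reference is attached
#'   as attribute `msc_reference`.
#' @export
preprocess <- function(spec, s, reference = NULL) {
  if (is.character(spec)) spec <- preprocess_spec(spec)
  stopifnot(inherits(spec, "preprocess_spec"))
  ref <- NULL
  out <- switch(spec$method,
    sg = sg_filter(s, spec$sg_window, spec$sg_polyorder, 0),
    snv = snv(s),
    msc = msc(s, reference),
    snv1d = sg_filter(snv(s), spec$sg_window, spec$sg_polyorder, 1),
    msc2d = {
      m <- msc(s, reference)
      ref <- attr(m, "msc_reference")
      sg_filter(m, spec$sg_window, spec$sg_polyorder, 2)
    }
  )
  if (spec$method == "msc") ref <- attr(out, "msc_reference")
  if (!is.null(ref)) attr(out, "msc_reference") <- ref
  out
}

preprocess_label <- function(method) {
  switch(method, sg = "SG", snv = "SNV", msc = "MSC",
         snv1d = "SNV + 1st D", msc2d = "MSC + 2nd D", method)
}
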