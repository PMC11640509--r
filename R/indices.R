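#' Streif harvest-maturity index
#'
#' `F / (SSC * SPI)`: flesh firmness over the product of soluble solids
#' content and starch pattern index. Falls as fruit matures.
#'
#' @param firmness Flesh firmness (N), non-negative.
#' @param ssc Soluble solids content (degrees Brix), positive.
#' @param spi Starch pattern index grade, positive.
#' @return Numeric vector.
#' @export
streif <- function(firmness, ssc, spi) {
  if (any(ssc <= 0)) stopf("ssc must be positive")
  if (any(spi <= 0)) stopf("spi must be positive")
  if (any(firmness < 0)) stopf("firmness must be non-negative")
  firmness / (ssc * spi)
}

#' Ripening index (RPI)
#'
#' `ln(100 * F * TA / SSC)`, a log-ratio of firmness and acidity to soluble
#' solids.
#'
#' @param firmness Flesh firmness (N), positive.
#' @param ta Titratable acidity, positive.
#' @param ssc Soluble solids content, positive.
#' @return Numeric vector.
#' @export
rpi <- function(firmness, ta, ssc) {
  if (any(firmness <= 0) || any(ta <= 0) || any(ssc <= 0))
    stopf("rpi arguments must all be positive")
  log(100 * firmness * ta / ssc)
}

#' Internal quality index (IQI)
#'
#' `ln(100 * F * TA * L* * h / (SSC * C*))`: the RPI extended with the CIELAB
#' lightness, hue angle and chroma. Identity: `iqi = rpi + ln(L * h / C)`.
#'
#' @param firmness Flesh firmness (N), positive.
#' @param ta Titratable acidity, positive.
#' @param L CIELAB lightness, positive.
#' @param h Hue angle (degrees), positive.
#' @param ssc Soluble solids content, positive.
#' @param C Chroma, positive.
#' @return Numeric vector.
#' @export
iqi <- function(firmness, ta, L, h, ssc, C) {
  if (any(c(firmness, ta, L, h, ssc, C) <= 0))
    stopf("iqi arguments must all be positive")
  log(100 * firmness * ta * L * h / (ssc * C))
}

#' Radar-chart specification for the VRPI
#'
#' Defines the ordered radar parameters, the normalization direction of each
#' (forward: larger raw value is riper; reverse: smaller raw value is riper)
#' and, once fitted, the per-parameter min-max normalization bounds.
#'
#' @param parameters Ordered parameter names (columns of the quality table).
#' @param direction Named character vector, `"forward"` or `"reverse"` per
#'   parameter. Default: SSC and a* forward; TA, Fp, Ff reverse.
#' @return An object of class `radar_spec` (unfitted: `bounds = NULL`).
#' @export
radar_spec <- function(parameters = c("ssc", "ta", "a", "Fp", "Ff"),
                       direction = c(ssc = "forward", ta = "reverse",
                                     a = "forward", Fp = "reverse",
                                     Ff = "reverse")) {
  if (length(parameters) < 3L) stopf("radar chart needs at least 3 parameters")
  if (!all(parameters %in% names(direction)))
    stopf("direction missing for: %s",
          paste(setdiff(parameters, names(direction)), collapse = ", "))
  if (!all(direction %in% c("forward", "reverse")))
    stopf("directions must be 'forward' or 'reverse'")
  structure(list(parameters = parameters,
                 direction = direction[parameters],
                 m = length(parameters),
                 alpha = 2 * pi / length(parameters),
                 bounds = NULL),
            class = "radar_spec")
}

#' Fit radar normalization bounds on a reference set
#'
#' Learns per-parameter min/max over the reference fruit. Forward parameters
#' normalize as `(x - min)/(max - min)`, reverse parameters as the complement
#' `1 - (x - min)/(max - min)`. Bounds fitted on a calibration set are reused
#' for new fruit, whose normalized values may then fall outside `[0, 1]`.
#'
#' @param quality A quality table containing the radar parameter columns.
#' @param spec A [radar_spec()].
#' @return The spec with `bounds` filled in.
#' @export
fit_radar_normalizer <- function(quality, spec = radar_spec()) {
  stopifnot(inherits(spec, "radar_spec"))
  if (nrow(quality) < 2L) stopf("need at least 2 fruit to fit normalization bounds")
  bounds <- t(vapply(spec$parameters, function(p) {
    x <- quality[[p]]
    if (is.null(x)) stopf("missing column %s", p)
    r <- range(x)
    if (r[1] == r[2]) stopf("constant parameter column: %s", p)
    r
  }, numeric(2)))
  colnames(bounds) <- c("min", "max")
  spec$bounds <- bounds
  spec
}

#' Normalize radar parameters
#'
#' @param quality A quality table.
#' @param spec A fitted [radar_spec()].
#' @return Matrix (fruit x parameters) of normalized, direction-adjusted
#'   values.
#' @export
radar_normalize <- function(quality, spec) {
  stopifnot(inherits(spec, "radar_spec"))
  if (is.null(spec$bounds)) stopf("radar_spec has no fitted bounds")
  out <- vapply(seq_along(spec$parameters), function(k) {
    p <- spec$parameters[k]
    b <- spec$bounds[k, ]
    v <- (quality[[p]] - b["min"]) / (b["max"] - b["min"])
    if (spec$direction[[p]] == "reverse") v <- 1 - v
    v
  }, numeric(nrow(quality)))
  out <- matrix(out, nrow = nrow(quality),
                dimnames = list(quality$sample_id, spec$parameters))
  out
}

#' Visual ripeness index: radar polygon area
#'
#' Area of the closed radar polygon over `m` normalized parameter values:
#' `(1/2) sin(2*pi/m) * (sum_{n=1}^{m-1} P_n P_{n+1} + P_1 P_m)`. Equals the
#' shoelace area of the polygon whose n-th vertex sits at radius `P_n` and
#' angle `2*pi*(n-1)/m`.
#'
#' @param p Numeric vector of `m >= 3` non-negative values, or a matrix with
#'   one fruit per row.
#' @param m Number of radar variables; defaults to `length(p)` / `ncol(p)`.
#' @return The polygon area (vector if `p` is a matrix).
#' @export
vrpi <- function(p, m = NULL) {
  if (is.matrix(p)) {
    m <- m %||% ncol(p)
    if (ncol(p) != m) stopf("expected %d radar values per fruit, got %d", m, ncol(p))
    if (any(p < 0)) stopf("radar values must be non-negative")
    if (m < 3L) stopf("radar chart needs at least 3 values")
    nxt <- c(2:m, 1)
    return(0.5 * sin(2 * pi / m) * rowSums(p * p[, nxt, drop = FALSE]))
  }
  m <- m %||% length(p)
  if (length(p) != m) stopf("expected %d radar values, got %d", m, length(p))
  if (any(p < 0)) stopf("radar values must be non-negative")
  if (m < 3L) stopf("radar chart needs at least 3 values")
  0.5 * sin(2 * pi / m) * (sum(p[-m] * p[-1]) + p[1] * p[m])
}

#' Compute the four maturity indices for every fruit
#'
#' Streif, RPI and IQI use flesh firmness `Ff`; the VRPI is the radar polygon
#' area over the normalized `spec` parameters (peel hardness `Fp` enters only
#' there).
#'
#' @param quality A quality table.
#' @param spec A [radar_spec()]; if unfitted, bounds are learned from
#'   `quality` itself.
#' @return Data frame with columns `sample_id`, `daf`, `streif`, `rpi`,
#'   `iqi`, `vrpi`.
#' @export
compute_index_table <- function(quality, spec = radar_spec()) {
  validate_quality(quality)
  if (is.null(spec$bounds)) spec <- fit_radar_normalizer(quality, spec)
  P <- radar_normalize(quality, spec)
  if (any(P < 0)) P <- pmax(P, 0)   # reference-bounds mode can undershoot
  data.frame(
    sample_id = quality$sample_id,
    daf = quality$daf,
    streif = streif(quality$Ff, quality$ssc, quality$spi),
    rpi = rpi(quality$Ff, quality$ta, quality$ssc),
    iqi = iqi(quality$Ff, quality$ta, quality$L, quality$h, quality$ssc, quality$C),
    vrpi = vrpi(P),
    stringsAsFactors = FALSE
  )
}

#' Batch summary of an index table
#'
#' @param indices Output of [compute_index_table()].
#' @return Data frame of per-DAF means and SDs for each index.
#' @export
index_batch_summary <- function(indices) {
  dafs <- sort(unique(indices$daf))
  do.call(rbind, lapply(dafs, function(d) {
    sub <- indices[indices$daf == d, c("streif", "rpi", "iqi", "vrpi")]
    data.frame(daf = d,
               streif = mean(sub$streif), streif_sd = sd(sub$streif),
               rpi = mean(sub$rpi), rpi_sd = sd(sub$rpi),
               iqi = mean(sub$iqi), iqi_sd = sd(sub$iqi),
               vrpi = mean(sub$vrpi), vrpi_sd = sd(sub$vrpi))
  }))
}

#' Pearson correlation matrix of the nine quality indices
#'
#' @param quality A quality table.
#' @return Symmetric 9x9 correlation matrix (SSC, TA, L, a, b, C, h, Fp, Ff).
#'   Constant columns give `NA` entries with a warning.
#' @export
quality_correlation <- function(quality) {
  validate_quality(quality)
  if (nrow(quality) < 3L) stopf("need at least 3 fruit for correlation analysis")
  cols <- c("ssc", "ta", "L", "a", "b", "C", "h", "Fp", "Ff")
  m <- as.matrix(quality[cols])
  const <- apply(m, 2, function(x) diff(range(x)) == 0)
  if (any(const)) warnf("constant column(s): %s; correlations undefined",
                        paste(cols[const], collapse = ", "))
  suppressWarnings(cor(m))
}
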