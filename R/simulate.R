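# NIR absorption bands of the synthetic pear spectra. Centers/widths in cm-1;
# base amplitude plus loadings on the standardized soluble-solids, firmness and
# acidity values of each fruit. Water bands near 5150/5620/6900/8310/10300 cm-1,
# C-H combination and overtone structure inside 4000-5000, 5555-5882, 8264-8696
# and 10300-12500 cm-1.
spectral_bands <- function() {
  data.frame(
    center = c(4400, 4760, 5150, 5620, 6900, 8310, 10300, 11500),
    sigma  = c(  70,   80,  110,   90,  120,  130,   160,   300),
    base   = c(0.35, 0.30, 1.00, 0.45, 0.65, 0.25,  0.18,  0.10),
    k_ssc  = c(0.20, 0.15, 0.00, 0.12, 0.05, 0.10,  0.06,  0.08),
    k_ff   = c(0.10, 0.00, 0.00, 0.08,-0.08, 0.00, -0.04,  0.05),
    k_ta   = c(-0.04, 0.00, 0.05, 0.00, 0.04, 0.00,  0.00,  0.00),
    # differential harvest-date effect: water bands decline with later
    # harvest relative to the C-H structure (week-to-week water loss), so the
    # batch signature survives scatter correction and derivatives
    k_daf  = c(0.00, 0.00, -0.08, 0.00, -0.05, 0.00, -0.03,  0.00)
  )
}

# Wavenumber windows carrying quality information (bands with nonzero loadings,
# +/- 2.5 sigma), used to check that wavelength selection lands on signal.
informative_ranges <- function() {
  b <- spectral_bands()
  keep <- b$k_ssc != 0 | b$k_ff != 0 | b$k_ta != 0
  cbind(lo = b$center[keep] - 2.5 * b$sigma[keep],
        hi = b$center[keep] + 2.5 * b$sigma[keep])
}

trajectory_value <- function(tr, q) tr[1] + (tr[2] - tr[1]) * q

#' Simulate the per-fruit quality table
#'
#' Draws the physicochemical quality record (SSC, TA, CIELAB color, peel
#' hardness Fp, flesh firmness Ff, starch pattern index SPI) for every quality
#' fruit of every harvest batch. Each fruit carries a latent maturity that
#' increases with harvest date; quality parameters are monotone affine in the
#' latent plus noise, calibrated so the batch means of the four computed
#' maturity indices track `config$batch_targets` (exactly at
#' `quality_noise = 0`, when indices are computed against
#' [radar_reference()] bounds). Titratable acidity is decoupled from the other
#' parameters so its pooled correlation with them stays near zero.
#'
#' @param config An [orchard_config()].
#' @return A data frame of class `quality_table` with columns `sample_id`,
#'   `daf`, `purpose`, `ssc`, `ta`, `L`, `a`, `b`, `C`, `h`, `Fp`, `Ff`, `spi`
#'   and an attribute `maturity` holding the latent per-fruit maturity.
#' @export
simulate_quality <- function(config) {
  stopifnot(inherits(config, "orchard_config"))
  cal <- calibrate_orchard(config)
  tr <- config$trajectories
  n_b <- config$samples_per_batch
  n <- config$n_batches * n_b
  qn <- config$quality_noise

  with_seed(config$seed, {
    batch <- rep(seq_len(config$n_batches), each = n_b)
    daf <- config$batch_targets$daf[batch]
    # latent maturity: batch position + within-batch spread
    q <- cal$P[batch] + cal$sigma_q[batch] * rnorm(n)

    eps <- function() config$param_noise * qn * rnorm(n)
    val <- function(nm) trajectory_value(tr[[nm]], q + eps())

    ssc <- val("ssc"); a <- val("a"); Fp <- val("Fp"); Ff <- val("Ff")
    L <- val("L"); b <- val("b"); C <- val("C")

    # TA: batch trend follows the calibrated trajectory; the within-batch
    # component runs against it (fixed decorrelation slope) plus its own noise
    q_ta <- cal$P[batch] + config$ta_decorr_lambda * (q - cal$P[batch]) +
      config$ta_vertex_noise * qn * rnorm(n)
    ta <- cal$ta0 + cal$ta_rng * (1 - q_ta)

    h <- cal$h0 + cal$h1 * (q + eps())
    spi_latent <- cal$spi0 + cal$spi1 * q + config$spi_noise * qn * rnorm(n)
    spi <- pmin(10, pmax(1, round(spi_latent)))

    out <- data.frame(
      sample_id = sprintf("B%d_F%02d", batch, rep(seq_len(n_b), config$n_batches)),
      daf = daf, purpose = "quality",
      ssc = ssc, ta = ta, L = L, a = a, b = b, C = C, h = h,
      Fp = pmax(0, Fp), Ff = pmax(0, Ff), spi = spi,
      stringsAsFactors = FALSE
    )
    validate_quality(out)
    attr(out, "maturity") <- q
    class(out) <- c("quality_table", "data.frame")
    out
  })
}

#' Reference radar normalization for the synthetic orchard
#'
#' Returns the [radar_spec()] whose normalization bounds are the generator's
#' design trajectories evaluated at latent maturity 0 and 1. Against these
#' reference bounds a fruit's normalized radar vertices equal its latent
#' maturity, so the zero-noise batch VRPI means reproduce the configured
#' targets exactly. Vertices of very ripe fruit may exceed 1, which the VRPI
#' area formula permits.
#'
#' @param config An [orchard_config()].
#' @return A fitted `radar_spec`.
#' @export
radar_reference <- function(config) {
  stopifnot(inherits(config, "orchard_config"))
  cal <- calibrate_orchard(config)
  tr <- config$trajectories
  spec <- radar_spec()
  ends <- list(
    ssc = tr$ssc,
    ta  = c(cal$ta0 + cal$ta_rng, cal$ta0),   # value at q = 0, q = 1
    a   = tr$a,
    Fp  = tr$Fp,
    Ff  = tr$Ff
  )
  bounds <- t(vapply(spec$parameters, function(p) range(ends[[p]]), numeric(2)))
  colnames(bounds) <- c("min", "max")
  spec$bounds <- bounds
  spec
}

#' Simulate NIR absorbance spectra from a quality table
#'
#' Each spectrum is a smooth baseline plus Gaussian absorption bands (water,
#' C-H and O-H overtone/combination bands; see the vignette) whose amplitudes
#' are affine in the fruit's SSC, Ff and TA. The baseline falls with
#' increasing maturity, so mean absorbance decreases with harvest date. The
#' noise model applies per-sample multiplicative/additive scatter and white
#' noise.
#'
#' @param quality A quality table (e.g. from [simulate_quality()]).
#' @param config An [orchard_config()].
#' @return A [spectra_set()] whose rows match `quality` rows; carries an
#'   attribute `informative_ranges`, the wavenumber windows with quality
#'   signal.
#' @export
simulate_spectra <- function(quality, config) {
  stopifnot(inherits(config, "orchard_config"))
  validate_quality(quality)
  n <- nrow(quality)
  if (n < 1L) stopf("quality table is empty")
  tr <- config$trajectories
  cal <- calibrate_orchard(config)
  w <- seq(config$wavenumber_min, config$wavenumber_max, length.out = config$n_points)
  bands <- spectral_bands()

  std <- function(x, tr2) (x - mean(tr2)) / (abs(diff(tr2)) / 2)
  s_ssc <- std(quality$ssc, tr$ssc)
  s_ff <- std(quality$Ff, tr$Ff)
  s_ta <- std(quality$ta, c(cal$ta0, cal$ta0 + cal$ta_rng))
  q_hat <- (quality$ssc - tr$ssc[1]) / (tr$ssc[2] - tr$ssc[1])
  # harvest-date baseline component: overall absorbance falls from week to
  # week (water loss / tissue drift), beyond what the quality traits carry
  daf_span <- diff(range(quality$daf))
  b_daf <- if (daf_span > 0) (quality$daf - min(quality$daf)) / daf_span
           else rep(0, n)

  # n x n_bands amplitude matrix, then project through the band shapes
  amp <- outer(rep(1, n), bands$base) +
    s_ssc %o% bands$k_ssc + s_ff %o% bands$k_ff + s_ta %o% bands$k_ta +
    b_daf %o% bands$k_daf
  shapes <- vapply(seq_len(nrow(bands)),
                   function(k) exp(-0.5 * ((w - bands$center[k]) / bands$sigma[k])^2),
                   numeric(length(w)))
  baseline <- outer(0.55 - 0.10 * q_hat - 0.08 * b_daf, rep(1, length(w))) +
    rep(1, n) %o% (0.05 * ((w - mean(w)) / (diff(range(w)) / 2))^2)
  X <- baseline + amp %*% t(shapes)

  with_seed(config$seed + 1L, {
    slope <- config$scatter_slope_sd * rnorm(n)
    offset <- config$scatter_offset_sd * rnorm(n)
    X <- X * (1 + slope) + offset
    if (config$noise_sd > 0)
      X <- X + matrix(rnorm(n * length(w), sd = config$noise_sd), n)
  })

  out <- spectra_set(X, w, quality$sample_id)
  attr(out, "informative_ranges") <- informative_ranges()
  out
}

#' Simulate the post-ripening batch table
#'
#' Generates the per-batch post-ripening record (raw a*, SSC, TA, edible rate
#' and rot rate after cold storage plus shelf period). The raw values are
#' affine embeddings of `config$postripening_profile`, so min-max
#' normalization with the conventional directions (TA and rot rate reversed)
#' recovers that profile exactly at zero noise; the rot rate is deliberately
#' non-monotone in harvest date.
#'
#' @param config An [orchard_config()].
#' @return A data frame of class `postripening_table` with columns `daf`, `a`,
#'   `ssc`, `ta`, `edible_rate`, `rot_rate` (rates in percent).
#' @export
simulate_postripening <- function(config) {
  stopifnot(inherits(config, "orchard_config"))
  pr <- config$postripening_profile
  if (nrow(pr) != config$n_batches)
    stopf("postripening_profile has %d rows but n_batches = %d",
          nrow(pr), config$n_batches)
  # raw bounds: c(min, max); reverse-coded columns are inverted back to raw
  ranges <- list(a = c(22, 34), ssc = c(11, 14), ta = c(0.15, 0.40),
                 edible_rate = c(78, 86), rot_rate = c(5, 25))
  reverse <- c(ta = TRUE, rot_rate = TRUE, a = FALSE, ssc = FALSE,
               edible_rate = FALSE)
  with_seed(config$seed + 2L, {
    out <- data.frame(daf = pr$daf)
    for (colname in c("a", "ssc", "ta", "edible_rate", "rot_rate")) {
      v <- pr[[colname]]
      if (reverse[[colname]]) v <- 1 - v
      r <- ranges[[colname]]
      raw <- r[1] + v * (r[2] - r[1]) +
        0.02 * (r[2] - r[1]) * config$quality_noise * rnorm(nrow(pr))
      out[[colname]] <- raw
    }
    out$edible_rate <- pmin(100, pmax(0, out$edible_rate))
    out$rot_rate <- pmin(100, pmax(0, out$rot_rate))
    class(out) <- c("postripening_table", "data.frame")
    out
  })
}

#' Inject lesioned outlier spectra
#'
#' Replaces `n_outliers` randomly chosen spectra with internally-lesioned
#' variants (an extra broad absorption band plus an elevated baseline), and
#' reports their ids so the outlier-removal policy (drop flagged fruit before
#' modeling) can be exercised.
#'
#' @param spectra A [spectra_set()].
#' @param n_outliers Number of spectra to replace (must be < sample count).
#' @param seed Integer seed for choosing which samples are lesioned.
#' @return A list with `spectra` (modified set) and `outlier_ids` (character).
#' @export
inject_outliers <- function(spectra, n_outliers, seed = 1) {
  stopifnot(inherits(spectra, "spectra_set"))
  n_outliers <- assert_count(n_outliers, "n_outliers", min = 0L)
  n <- nrow(spectra$absorbance)
  if (n_outliers >= n) stopf("n_outliers (%d) must be smaller than the sample count (%d)",
                             n_outliers, n)
  if (n_outliers == 0L) return(list(spectra = spectra, outlier_ids = character(0)))
  w <- spectra$wavenumbers
  with_seed(seed, {
    idx <- sort(sample.int(n, n_outliers))
    lesion <- 0.6 * exp(-0.5 * ((w - 6500) / 800)^2)
    for (i in idx)
      spectra$absorbance[i, ] <- spectra$absorbance[i, ] + lesion + 0.35
    list(spectra = spectra, outlier_ids = spectra$sample_ids[idx])
  })
}

#' Drop samples from a spectra set and quality table by id
#'
#' @param spectra A [spectra_set()].
#' @param quality Optional quality table aligned with `spectra`.
#' @param ids Character vector of sample ids to remove.
#' @return A list with `spectra` and (if given) `quality`.
#' @export
drop_samples <- function(spectra, quality = NULL, ids) {
  stopifnot(inherits(spectra, "spectra_set"))
  keep <- !(spectra$sample_ids %in% ids)
  if (!any(keep)) stopf("dropping all samples")
  out <- list(spectra = spectra[keep, ])
  if (!is.null(quality)) {
    qkeep <- !(quality$sample_id %in% ids)
    q <- quality[qkeep, , drop = FALSE]
    attr(q, "maturity") <- attr(quality, "maturity")[qkeep]
    out$quality <- q
  }
  out
}
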