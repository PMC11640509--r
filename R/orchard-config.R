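#' Default per-batch maturity-index targets
#'
#' Per-harvest (days after flowering, DAF) means and standard deviations of the
#' four maturity indices that the synthetic orchard is calibrated to reproduce:
#' Streif index, ripening index (RPI), internal quality index (IQI) and the
#' radar-area visual ripeness index (VRPI).
#'
#' @return A data frame with one row per harvest batch and columns `daf`,
#'   `streif`, `streif_sd`, `rpi`, `rpi_sd`, `iqi`, `iqi_sd`, `vrpi`, `vrpi_sd`.
#' @export
default_batch_targets <- function() {
  data.frame(
    daf       = c(90L, 97L, 104L, 111L),
    streif    = c(0.57, 0.55, 0.42, 0.41),
    streif_sd = c(0.17, 0.19, 0.11, 0.13),
    rpi       = c(2.28, 2.22, 2.02, 1.94),
    rpi_sd    = c(0.27, 0.19, 0.20, 0.19),
    iqi       = c(8.37, 8.30, 8.08, 8.02),
    iqi_sd    = c(0.16, 0.23, 0.18, 0.25),
    vrpi      = c(1.59, 1.81, 2.27, 2.63),
    vrpi_sd   = c(0.19, 0.24, 0.37, 0.55)
  )
}

#' Default post-ripening batch profile
#'
#' Min-max-normalized, direction-adjusted post-ripening quality values per
#' harvest batch (peel redness a*, soluble solids SSC, titratable acidity TA,
#' edible rate and rot rate; TA and rot rate already reverse-coded so that
#' larger is riper). The synthetic post-ripening table is calibrated so that
#' normalizing it reproduces this profile at zero noise.
#'
#' @return A data frame with columns `daf`, `a`, `ssc`, `ta`, `edible_rate`,
#'   `rot_rate`.
#' @export
default_postripening_profile <- function() {
  data.frame(
    daf         = c(90L, 97L, 104L, 111L),
    a           = c(0.00, 0.38, 0.60, 1.00),
    ssc         = c(0.00, 0.76, 0.62, 1.00),
    ta          = c(0.00, 0.00, 1.00, 1.00),
    edible_rate = c(0.00, 0.71, 1.00, 0.71),
    rot_rate    = c(0.37, 0.33, 1.00, 0.00)
  )
}

# Quality-parameter trajectories: value at latent maturity q = 0 and q = 1.
# Reverse-direction parameters (TA, Fp, Ff) decrease with q.
default_trajectories <- function() {
  list(
    ssc = c(9, 13),     # soluble solids, degrees Brix
    a   = c(-5, 35),    # CIELAB a* (red-green)
    Fp  = c(70, 30),    # peel hardness, N
    Ff  = c(48, 24),    # flesh firmness, N
    L   = c(52, 47),    # CIELAB lightness
    b   = c(17, 23),    # CIELAB b* (blue-yellow)
    C   = c(28, 32)     # chroma
  )
}

#' Synthetic orchard configuration
#'
#' Bundles all parameters of the synthetic 'Starkrimson' orchard: the study
#' design (four weekly harvests at 90/97/104/111 DAF, 60 quality fruit per
#' batch), the FT-NIR acquisition grid (4000-12500 cm-1), noise magnitudes,
#' and the per-batch maturity-index targets the generator is calibrated to.
#'
#' @param n_batches Number of harvest batches.
#' @param samples_per_batch Fruit per batch used for quality determination.
#' @param storage_per_batch Fruit per batch placed in cold storage for the
#'   post-ripening assessment.
#' @param wavenumber_min,wavenumber_max Spectral range in cm-1.
#' @param n_points Number of spectral points on the wavenumber grid.
#' @param resolution Nominal instrument resolution in cm-1 (metadata only).
#' @param seed Integer seed; all generator randomness derives from it.
#' @param noise_sd Standard deviation of additive white spectral noise
#'   (absorbance units).
#' @param scatter_slope_sd,scatter_offset_sd Standard deviations of the
#'   per-sample multiplicative and additive scatter terms.
#' @param quality_noise Scale factor (>= 0) on all quality-table noise terms,
#'   including the within-batch maturity spread. Zero gives a deterministic
#'   table whose batch index means reproduce `batch_targets` exactly.
#' @param batch_targets Per-batch index targets, see [default_batch_targets()].
#' @param postripening_profile Normalized post-ripening profile, see
#'   [default_postripening_profile()].
#'
#' @details The within-batch titratable-acidity trend is decoupled from the
#'   other quality parameters by a fixed decorrelation slope (see the package
#'   vignette); this keeps the pooled Pearson correlation between TA and the
#'   remaining indices near zero while preserving the calibrated VRPI spread.
#'
#' @return An object of class `orchard_config`.
#' @export
orchard_config <- function(n_batches = 4,
                           samples_per_batch = 60,
                           storage_per_batch = 40,
                           wavenumber_min = 4000,
                           wavenumber_max = 12500,
                           n_points = 2203,
                           resolution = 8,
                           seed = 1,
                           noise_sd = 0.005,
                           scatter_slope_sd = 0.05,
                           scatter_offset_sd = 0.02,
                           quality_noise = 1,
                           batch_targets = default_batch_targets(),
                           postripening_profile = default_postripening_profile()) {
  n_batches <- assert_count(n_batches, "n_batches")
  samples_per_batch <- assert_count(samples_per_batch, "samples_per_batch")
  storage_per_batch <- assert_count(storage_per_batch, "storage_per_batch", min = 0L)
  n_points <- assert_count(n_points, "n_points", min = 2L)
  seed <- assert_count(seed, "seed", min = 0L)
  wavenumber_min <- assert_number(wavenumber_min, "wavenumber_min", min = 0)
  wavenumber_max <- assert_number(wavenumber_max, "wavenumber_max")
  if (wavenumber_max <= wavenumber_min)
    stopf("wavenumber_max must exceed wavenumber_min")
  for (nm in c("noise_sd", "scatter_slope_sd", "scatter_offset_sd", "quality_noise"))
    assert_number(get(nm), nm, min = 0)

  bt <- batch_targets
  need <- c("daf", "streif", "rpi", "iqi", "vrpi",
            "streif_sd", "rpi_sd", "iqi_sd", "vrpi_sd")
  if (!is.data.frame(bt) || !all(need %in% names(bt)))
    stopf("batch_targets must contain columns: %s", paste(need, collapse = ", "))
  if (nrow(bt) != n_batches)
    stopf("batch_targets has %d rows but n_batches = %d", nrow(bt), n_batches)
  if (any(bt$vrpi <= 0)) stopf("VRPI targets must be positive")
  sds <- as.matrix(bt[grep("_sd$", names(bt))])
  if (any(sds <= 0)) stopf("batch target SDs must all be positive (zero-SD target)")
  if (is.unsorted(bt$daf, strictly = TRUE)) stopf("batch_targets$daf must be strictly increasing")

  structure(
    list(
      n_batches = n_batches,
      samples_per_batch = samples_per_batch,
      storage_per_batch = storage_per_batch,
      wavenumber_min = wavenumber_min,
      wavenumber_max = wavenumber_max,
      n_points = n_points,
      resolution = resolution,
      seed = seed,
      noise_sd = noise_sd,
      scatter_slope_sd = scatter_slope_sd,
      scatter_offset_sd = scatter_offset_sd,
      quality_noise = quality_noise,
      batch_targets = bt,
      postripening_profile = postripening_profile,
      trajectories = default_trajectories(),
      param_noise = 0.02,       # per-parameter noise on the latent scale
      spi_noise = 0.35,         # starch-grade jitter before rounding
      ta_decorr_lambda = -0.493,# within-batch TA slope vs latent maturity
      ta_vertex_noise = 0.05    # independent TA noise on the latent scale
    ),
    class = "orchard_config"
  )
}

#' @export
print.orchard_config <- function(x, ...) {
  cat("Synthetic orchard configuration\n")
  cat(sprintf("  %d batches (DAF %s), %d quality + %d storage fruit per batch\n",
              x$n_batches, paste(x$batch_targets$daf, collapse = "/"),
              x$samples_per_batch, x$storage_per_batch))
  cat(sprintf("  spectra: %d points, %g-%g cm-1, noise sd %g\n",
              x$n_points, x$wavenumber_min, x$wavenumber_max, x$noise_sd))
  invisible(x)
}

# Regular-polygon area with unit circumradius for m vertices.
polygon_area_unit <- function(m) 0.5 * sin(2 * pi / m) * m

# Derived per-batch constants: latent positions, spreads and the affine maps
# for TA, hue and starch grade, solved in closed form from the batch targets.
calibrate_orchard <- function(config) {
  bt <- config$batch_targets
  tr <- config$trajectories
  A5 <- polygon_area_unit(5L)

  P <- sqrt(bt$vrpi / A5)                      # latent maturity per batch
  lam <- config$ta_decorr_lambda
  # VRPI sensitivity to the latent: four shared vertices plus the lambda-coupled
  # TA vertex; d(area)/dq = 0.5*sin(72deg) * (7 + 2*lambda) * P at equal vertices
  dv <- 0.5 * sin(2 * pi / 5) * (7 + 2 * lam) * P
  sigma_q <- config$quality_noise * bt$vrpi_sd / dv

  at <- function(tr2, q) tr2[1] + (tr2[2] - tr2[1]) * q
  SSC <- at(tr$ssc, P); FF <- at(tr$Ff, P)

  # TA affine in (1 - q), least squares against the RPI targets
  ta_target <- exp(bt$rpi) * SSC / (100 * FF)
  f <- lm.fit(cbind(1, 1 - P), ta_target)$coefficients
  ta0 <- unname(f[1]); ta_rng <- unname(f[2])
  if (!is.finite(ta0) || !is.finite(ta_rng) || ta0 + min(0, ta_rng) <= 0)
    stopf("batch targets yield a non-positive titratable-acidity trajectory")
  TA <- ta0 + ta_rng * (1 - P)

  rpi_implied <- log(100 * FF * TA / SSC)

  # hue affine in q, least squares against the IQI targets
  L <- at(tr$L, P); C <- at(tr$C, P)
  h_target <- exp(bt$iqi - rpi_implied) * C / L
  f <- lm.fit(cbind(1, P), h_target)$coefficients
  h0 <- unname(f[1]); h1 <- unname(f[2])

  # starch grade affine in q, least squares against the Streif targets
  spi_target <- FF / (SSC * bt$streif)
  f <- lm.fit(cbind(1, P), spi_target)$coefficients
  s0 <- unname(f[1]); s1 <- unname(f[2])

  list(P = P, sigma_q = sigma_q, ta0 = ta0, ta_rng = ta_rng,
       h0 = h0, h1 = h1, spi0 = s0, spi1 = s1)
}
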