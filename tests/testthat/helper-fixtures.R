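# Small orchard: fewer spectral points so unit tests stay fast.
small_config <- function(seed = 1, ...) {
  orchard_config(seed = seed, n_points = 300, ...)
}

# Seeded evaluation without disturbing the test RNG stream.
with_seed_test <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}

# Shoelace polygon area for radar vertices: independent oracle for vrpi().
shoelace_radar_area <- function(p) {
  m <- length(p)
  theta <- 2 * pi * (seq_len(m) - 1) / m
  x <- p * cos(theta); y <- p * sin(theta)
  nxt <- c(2:m, 1)
  abs(sum(x * y[nxt] - x[nxt] * y)) / 2
}

# Regression problem whose signal lives in three known wavelength bands.
make_band_problem <- function(seed, n = 60, p = 120) {
  set.seed(seed)
  bands <- list(11:20, 51:60, 91:100)
  X <- matrix(rnorm(n * p, sd = 0.05), n, p)
  h <- matrix(rnorm(n * 3), n, 3)
  for (k in 1:3) X[, bands[[k]]] <- X[, bands[[k]]] + h[, k]
  y <- h %*% c(1, -0.7, 0.5) + rnorm(n, sd = 0.05)
  list(X = X, y = as.vector(y), support = unlist(bands))
}

# Memoised full-scale pipeline (n = 240 fruit, 2203 points): quantitative
# SNV+1stD VRPI model plus cross-validated classification, per seed.
.pipeline_cache <- new.env(parent = emptyenv())

full_pipeline <- function(seed, algos = c("svm", "knn", "nn", "nb", "lda")) {
  key <- paste0("seed", seed, "_", paste(algos, collapse = "-"))
  if (!is.null(.pipeline_cache[[key]])) return(.pipeline_cache[[key]])
  cfg <- orchard_config(seed = seed)
  q <- simulate_quality(cfg)
  s <- simulate_spectra(q, cfg)
  inj <- inject_outliers(s, 2, seed = cfg$seed)
  d <- drop_samples(inj$spectra, q, inj$outlier_ids)
  quant <- suppressWarnings(run_quantitative(
    d$spectra, d$quality, methods = "snv1d", index_names = "vrpi",
    radar = radar_reference(cfg), cars = cars_config(seed = seed),
    n_removed = 2, seed = seed))
  batch <- post_ripeness_score(simulate_postripening(cfg))
  fs <- fruit_scores(quant$indices$vrpi, d$quality$daf, batch)
  sel <- list(snv1d = quant$cells[["snv1d.vrpi"]]$model$selected)
  qual <- suppressWarnings(run_qualitative(
    d$spectra, fs$label, sel, algos = algos, validations = "cv", seed = seed))
  out <- list(quant = quant, labels = fs$label, qual = qual,
              reports = attr(qual, "reports"),
              rp2 = quant$table$rp2, rmsep = quant$table$rmsep,
              n_selected = quant$table$variables,
              cv_ca = max(qual$ca))
  .pipeline_cache[[key]] <- out
  out
}
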