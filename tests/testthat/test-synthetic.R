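test_that("quality table has the study layout and is reproducible under seed", {
  cfg <- small_config(seed = 1)
  q1 <- simulate_quality(cfg)
  q2 <- simulate_quality(cfg)
  expect_identical(q1, q2)
  expect_equal(nrow(q1), 240)
  expect_equal(unname(table(q1$daf)), rep(60L, 4), ignore_attr = TRUE)
  expect_true(all(q1$spi == round(q1$spi) & q1$spi >= 1 & q1$spi <= 10))
  # latent maturity batch means strictly increase with DAF
  m <- attr(q1, "maturity")
  means <- tapply(m, q1$daf, mean)
  expect_true(all(diff(means) > 0))
})

test_that("zero-noise quality reproduces the VRPI batch targets exactly", {
  cfg <- small_config(seed = 4, quality_noise = 0, noise_sd = 0,
                      scatter_slope_sd = 0, scatter_offset_sd = 0)
  q <- simulate_quality(cfg)
  idx <- compute_index_table(q, radar_reference(cfg))
  means <- tapply(idx$vrpi, idx$daf, mean)
  expect_equal(as.vector(means), cfg$batch_targets$vrpi, tolerance = 1e-9)
})

test_that("noisy quality keeps all four index batch means within 15% of targets", {
  cfg <- small_config(seed = 2)
  q <- simulate_quality(cfg)
  idx <- compute_index_table(q, radar_reference(cfg))
  tgt <- cfg$batch_targets
  for (nm in c("streif", "rpi", "iqi", "vrpi")) {
    means <- unname(tapply(idx[[nm]], idx$daf, mean))
    expect_true(all(abs(means - tgt[[nm]]) / tgt[[nm]] < 0.15),
                info = nm)
  }
})

test_that("titratable acidity is near-independent of the other quality indices", {
  cm <- quality_correlation(simulate_quality(small_config(seed = 3)))
  others <- setdiff(colnames(cm), "ta")
  expect_true(all(abs(cm["ta", others]) < 0.3))
})

test_that("config validation rejects degenerate designs", {
  expect_error(orchard_config(samples_per_batch = 0), "samples_per_batch")
  bt <- default_batch_targets(); bt$vrpi_sd[2] <- 0
  expect_error(orchard_config(batch_targets = bt), "zero-SD")
  expect_error(orchard_config(n_points = 1), "n_points")
})

test_that("spectra have the configured grid and identical fruit give identical spectra", {
  cfg <- small_config(seed = 5, quality_noise = 0, noise_sd = 0,
                      scatter_slope_sd = 0, scatter_offset_sd = 0)
  q <- simulate_quality(cfg)
  s <- simulate_spectra(q, cfg)
  expect_equal(ncol(s$absorbance), cfg$n_points)
  expect_equal(nrow(s$absorbance), nrow(q))
  # same batch + zero noise -> identical quality -> identical spectra
  i <- which(q$daf == 97)[1:2]
  expect_equal(s$absorbance[i[1], ], s$absorbance[i[2], ])
  # mean absorbance decreases with harvest date
  mabs <- tapply(rowMeans(s$absorbance), q$daf, mean)
  expect_true(all(diff(mabs) < 0))
})

test_that("SNV-preprocessed synthetic spectra carry recoverable SSC signal", {
  cfg <- small_config(seed = 6)
  q <- simulate_quality(cfg)
  s <- simulate_spectra(q, cfg)
  n <- nrow(q)
  test_idx <- seq_len(n) %% 3 == 0   # held-out third
  X <- snv(s)$absorbance
  fit <- pls_fit(X[!test_idx, ], q$ssc[!test_idx], 2)
  ev <- evaluate_regression(q$ssc[test_idx], predict(fit, X[test_idx, ]))
  expect_gt(ev$r2, 0.8)
})

test_that("post-ripening table matches the design profile and is seeded", {
  cfg <- small_config(seed = 1)
  p1 <- simulate_postripening(cfg)
  expect_identical(p1, simulate_postripening(cfg))
  expect_equal(nrow(p1), 4)
  expect_true(all(p1$rot_rate >= 0 & p1$rot_rate <= 100))
  expect_true(all(p1$edible_rate >= 0 & p1$edible_rate <= 100))
  ns <- post_ripeness_score(p1)
  expect_true(all(as.matrix(ns[c("a", "ssc", "ta", "edible_rate", "rot_rate")]) >= 0))
  expect_true(all(as.matrix(ns[c("a", "ssc", "ta", "edible_rate", "rot_rate")]) <= 1))
  # zero-noise profile normalizes back to the configured reference exactly
  cfg0 <- small_config(seed = 1, quality_noise = 0)
  ns0 <- post_ripeness_score(simulate_postripening(cfg0))
  ref <- default_postripening_profile()
  expect_equal(as.matrix(ns0[names(ref)[-1]]), as.matrix(ref[-1]),
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("outlier injection flags detectable lesioned spectra", {
  cfg <- small_config(seed = 7)
  q <- simulate_quality(cfg)
  s <- simulate_spectra(q, cfg)
  inj <- inject_outliers(s, 2, seed = 11)
  expect_length(inj$outlier_ids, 2)
  d <- drop_samples(inj$spectra, q, inj$outlier_ids)
  expect_equal(nrow(d$spectra$absorbance), 238)
  expect_equal(nrow(d$quality), 238)
  # identity at zero outliers
  expect_identical(inject_outliers(s, 0)$spectra, s)
  expect_error(inject_outliers(s, nrow(s$absorbance)), "smaller")
  # lesioned spectra sit far outside the clean PCA-2 subspace
  clean <- s$absorbance
  pc <- prcomp(clean, rank. = 2)
  md <- function(X) {
    sc <- scale(X %*% pc$rotation, center = colMeans(pc$x), scale = FALSE)
    stats::mahalanobis(sc, c(0, 0), stats::cov(pc$x))
  }
  cut <- quantile(md(clean), 0.99)
  out_rows <- match(inj$outlier_ids, s$sample_ids)
  expect_true(all(md(inj$spectra$absorbance[out_rows, , drop = FALSE]) > cut))
})
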