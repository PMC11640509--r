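test_that("SNV standardizes every spectrum and is idempotent", {
  expect_equal(as.vector(snv(matrix(c(1, 2, 3), 1))), c(-1, 0, 1))
  set.seed(1)
  X <- matrix(rnorm(200, sd = 3) + 5, 10, 20)
  Z <- snv(X)
  expect_lt(max(abs(rowMeans(Z))), 1e-12)
  expect_lt(max(abs(apply(Z, 1, sd) - 1)), 1e-12)
  expect_equal(snv(Z), Z, tolerance = 1e-12)
  expect_error(snv(matrix(1, 2, 5)), "constant spectrum")
})

test_that("MSC inverts affine scatter exactly and leaves the reference unchanged", {
  set.seed(2)
  ref <- sin(seq(0, 3, length.out = 50)) + 2
  X <- rbind(ref, 2 * ref + 3, 0.5 * ref - 1)
  out <- msc(X, reference = ref)
  for (i in 1:3) expect_equal(unname(out[i, ]), unname(ref), tolerance = 1e-10)
  # mean-reference MSC collapses scatter-only variation at a flat wavenumber
  cfg <- small_config(seed = 8, quality_noise = 0, noise_sd = 0)
  q <- simulate_quality(cfg)
  q <- q[q$daf == 90, ][rep(1, 30), ]       # identical fruit
  q$sample_id <- paste0("S", 1:30)
  s <- simulate_spectra(q, cfg)             # scatter still active
  flat <- which.min(abs(s$wavenumbers - 12400))
  v_before <- var(s$absorbance[, flat])
  v_after <- var(msc(s)$absorbance[, flat])
  expect_lt(v_after * 10, v_before)
  expect_error(msc(rbind(ref, rep(mean(ref), 50)) , reference = ref), "slope")
})

test_that("Savitzky-Golay filter reproduces polynomials and their derivatives", {
  w <- seq(4000, 4100, by = 2)
  s <- spectra_set(rbind(w^2, 3 * w + 7), c(w))
  d1 <- sg_filter(s, window = 7, polyorder = 2, deriv = 1)
  interior <- 4:(length(w) - 3)
  expect_equal(d1$absorbance[1, interior], 2 * w[interior], tolerance = 1e-8)
  d0 <- sg_filter(s, window = 7, polyorder = 2, deriv = 0)
  expect_equal(d0$absorbance[2, ], 3 * w + 7, tolerance = 1e-10)
  d2 <- sg_filter(s, window = 9, polyorder = 3, deriv = 2)
  expect_equal(d2$absorbance[1, interior], rep(2, length(interior)),
               tolerance = 1e-8)
  # smoothing reduces white-noise variance
  set.seed(3)
  noise <- matrix(rnorm(500), 1)
  sm <- sg_filter(noise, window = 15, polyorder = 2, deriv = 0)
  expect_lt(var(as.vector(sm)), var(as.vector(noise)))
  expect_error(sg_filter(noise, window = 8), "odd")
  expect_error(sg_filter(noise, window = 5, polyorder = 5), "exceed")
  expect_error(sg_filter(noise, window = 7, polyorder = 2, deriv = 3), "deriv")
})

test_that("preprocess() composes scatter correction before the derivative", {
  cfg <- small_config(seed = 9)
  s <- simulate_spectra(simulate_quality(cfg), cfg)
  expect_equal(preprocess("snv", s)$absorbance, snv(s)$absorbance)
  expect_equal(preprocess("snv1d", s)$absorbance,
               sg_filter(snv(s), 15, 2, 1)$absorbance)
  expect_equal(preprocess("msc2d", s)$absorbance,
               sg_filter(msc(s), 15, 3, 2)$absorbance)
  for (m in c("sg", "snv", "msc", "snv1d", "msc2d"))
    expect_equal(dim(preprocess(m, s)$absorbance), dim(s$absorbance))
  expect_error(preprocess_spec("osc"), "arg")
  # preprocessing is per-sample: permuting samples commutes
  perm <- c(5, 1, 3, 2, 4)
  sub <- s[1:5, ]
  expect_equal(preprocess("snv1d", sub)$absorbance[perm, ],
               preprocess("snv1d", sub[perm, ])$absorbance, ignore_attr = TRUE)
})
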