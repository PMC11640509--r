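test_that("index formulas match direct arithmetic", {
  expect_equal(streif(5, 10, 5), 0.1)
  expect_equal(streif(0, 10, 5), 0)
  expect_equal(streif(28.5, 10, 5), 0.57)
  expect_error(streif(5, 0, 5), "positive")
  expect_equal(rpi(5, 0.2, 10), log(10))
  expect_equal(rpi(1, 0.1, 10), 0)               # 100*F*TA == SSC
  expect_equal(rpi(exp(1) * 5, 0.2, 10), rpi(5, 0.2, 10) + 1)
  expect_equal(iqi(5, 0.2, 50, 40, 10, 50), log(400))
  # cancellation: L = C and h = SSC/(100 F TA)
  expect_equal(iqi(5, 0.2, 30, 10 / (100 * 5 * 0.2), 10, 30), 0)
  # algebraic identity on random inputs
  set.seed(4)
  for (i in 1:20) {
    v <- runif(6, 0.1, 50)
    expect_equal(iqi(v[1], v[2], v[3], v[4], v[5], v[6]),
                 rpi(v[1], v[2], v[5]) + log(v[3] * v[4] / v[6]))
  }
})

test_that("radar normalization respects bounds and directions", {
  q <- data.frame(ssc = c(10, 20), ta = c(10, 20), a = c(0, 1),
                  Fp = c(0, 1), Ff = c(0, 1), sample_id = c("a", "b"))
  spec <- fit_radar_normalizer(q)
  expect_equal(unname(spec$bounds["ssc", ]), c(10, 20))
  mid <- data.frame(ssc = 15, ta = 15, a = 0.5, Fp = 0.5, Ff = 0.5,
                    sample_id = "m")
  P <- radar_normalize(mid, spec)
  expect_equal(unname(P[1, "ssc"]), 0.5)   # forward
  expect_equal(unname(P[1, "ta"]), 0.5)    # reverse at midpoint
  lo <- data.frame(ssc = 10, ta = 10, a = 0, Fp = 0, Ff = 0, sample_id = "l")
  Pl <- radar_normalize(lo, spec)
  expect_equal(unname(Pl[1, "ta"]), 1)     # reverse: raw minimum -> 1
  # forward + reverse of the same value sum to 1
  expect_equal(unname(Pl[1, "ssc"] + Pl[1, "ta"]), 1)
  Ptrain <- radar_normalize(q, spec)
  expect_true(all(Ptrain >= 0 & Ptrain <= 1))
  q$ssc <- c(10, 10)
  expect_error(fit_radar_normalizer(q), "constant")
})

test_that("VRPI equals the shoelace polygon area", {
  expect_equal(vrpi(rep(1, 5)), 2.5 * sin(2 * pi / 5))
  expect_equal(vrpi(rep(1, 5)), 2.377641, tolerance = 1e-6)
  expect_equal(vrpi(rep(1, 4)), 2)          # unit square rotated 45 degrees
  expect_equal(vrpi(rep(0, 5)), 0)
  set.seed(5)
  for (m in 3:8) {
    for (rep_i in 1:25) {
      p <- runif(m, 0, 2)
      expect_equal(vrpi(p), shoelace_radar_area(p), tolerance = 1e-10)
    }
  }
  expect_error(vrpi(c(-1, 1, 1)), "non-negative")
  expect_error(vrpi(c(1, 1), m = 3), "expected")
})

test_that("VRPI is monotone non-decreasing in each vertex", {
  set.seed(6)
  for (rep_i in 1:20) {
    p <- runif(5, 0, 1.5)
    base <- vrpi(p)
    for (j in 1:5) {
      p2 <- p; p2[j] <- p2[j] + 0.1
      expect_gte(vrpi(p2), base)
    }
  }
})

test_that("index table is row-stable and handles single fruit", {
  q <- simulate_quality(small_config(seed = 10))
  spec <- fit_radar_normalizer(q)
  idx <- compute_index_table(q, spec)
  expect_equal(nrow(idx), nrow(q))
  perm <- sample(nrow(q))
  idx_p <- compute_index_table(q[perm, ], spec)
  expect_equal(idx_p$vrpi, idx$vrpi[perm])
  expect_equal(idx_p$sample_id, idx$sample_id[perm])
  one <- compute_index_table(q[1, , drop = FALSE], spec)
  expect_equal(nrow(one), 1)
  expect_equal(one$vrpi, idx$vrpi[1])
})

test_that("quality correlation matrix is a proper correlation matrix", {
  q <- simulate_quality(small_config(seed = 11))
  cm <- quality_correlation(q)
  expect_equal(dim(cm), c(9L, 9L))
  expect_equal(unname(diag(cm)), rep(1, 9))
  expect_equal(cm, t(cm))
  # perfect linear association
  q2 <- q; q2$L <- 2 * q2$ssc + 1; q2$b <- -q2$ssc
  cm2 <- quality_correlation(q2)
  expect_equal(unname(cm2["ssc", "L"]), 1)
  expect_equal(unname(cm2["ssc", "b"]), -1)
  q3 <- q; q3$b <- 20
  expect_warning(cm3 <- quality_correlation(q3), "constant")
  expect_true(is.na(cm3["b", "ssc"]))
})
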