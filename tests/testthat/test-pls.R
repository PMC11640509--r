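test_that("Kennard-Stone picks max-min-distance samples deterministically", {
  X <- matrix(c(0, 1, 10), ncol = 1)
  sp <- kennard_stone_split(X, 2)
  expect_equal(sp$train, c(1, 3))
  expect_equal(sp$test, 2)
  # third pick by max-min distance: 5 (min dist 5) beats 4 (min dist 4)
  X2 <- matrix(c(0, 4, 5, 10), ncol = 1)
  sp2 <- kennard_stone_split(X2, 3)
  expect_setequal(sp2$train, c(1, 4, 3))   # {0, 10, 5}
  # genuine tie broken toward the lowest index
  X2b <- matrix(c(0, 4, 6, 10), ncol = 1)
  expect_setequal(kennard_stone_split(X2b, 3)$train, c(1, 4, 2))
  expect_error(kennard_stone_split(X2, 4), "smaller")
  # permutation-invariant up to ties
  set.seed(7)
  X3 <- matrix(rnorm(60), 20, 3)
  perm <- sample(20)
  a <- kennard_stone_split(X3, 12)$train
  b <- kennard_stone_split(X3[perm, ], 12)$train
  expect_setequal(perm[b], a)
})

test_that("study split sizes come out at 180/58", {
  sz <- ks_split_sizes(240, n_removed = 2)
  expect_equal(sz$n_train, 180L)
  expect_equal(sz$n_test, 58L)
})

test_that("NIPALS PLS recovers exact linear responses and matches OLS in full rank", {
  set.seed(8)
  X <- matrix(rnorm(160), 20, 8)
  beta <- rnorm(8)
  y <- as.vector(X %*% beta) + 2
  fit <- pls_fit(X, y, 8)
  expect_lt(sqrt(mean((predict(fit, X) - y)^2)), 1e-8)
  # one-variable PLS equals simple least squares
  x1 <- matrix(rnorm(30), ncol = 1)
  y1 <- 3 * x1[, 1] + rnorm(30)
  f1 <- pls_fit(x1, y1, 1)
  ols1 <- lm(y1 ~ x1[, 1])
  expect_equal(unname(f1$coefficients[1, 1]), unname(coef(ols1)[2]), tolerance = 1e-10)
  # full-component PLS == normal-equations OLS on random full-rank problems
  for (rep_i in 1:5) {
    Xr <- matrix(rnorm(160), 20, 8)
    yr <- as.vector(Xr %*% rnorm(8)) + rnorm(20)
    fr <- pls_fit(Xr, yr, 8)
    Xc <- cbind(1, Xr)
    b_ols <- solve(crossprod(Xc), crossprod(Xc, yr))
    pred_ols <- as.vector(Xc %*% b_ols)
    expect_equal(predict(fr, Xr), pred_ols, tolerance = 1e-6)
  }
})

test_that("NIPALS scores are mutually orthogonal", {
  set.seed(9)
  X <- matrix(rnorm(600), 30, 20)
  y <- rnorm(30)
  fit <- pls_fit(X, y, 8)
  G <- crossprod(fit$scores)
  off <- G - diag(diag(G))
  expect_lt(max(abs(off)) / max(diag(G)), 1e-8)
  # predicting at the training mean returns the response mean
  expect_equal(predict(fit, matrix(fit$x_mean, 1)), fit$y_mean)
})

test_that("cross-validation selects the true rank for noiseless responses", {
  set.seed(10)
  X <- matrix(rnorm(300), 50, 6)
  y <- as.vector(X %*% c(1, -1, 0.5, 0, 0, 0))
  cv <- pls_cross_validate(X, y, folds = 5, max_components = 6, seed = 1)
  expect_lt(cv$rmsecv_min, 1e-8)
  expect_equal(cv$rmsecv, pls_cross_validate(X, y, folds = 5, max_components = 6,
                                             seed = 1)$rmsecv)
  # pure-noise response has no cross-validated skill (majority of seeds)
  low <- vapply(1:5, function(sd) {
    set.seed(100 + sd)
    Xn <- matrix(rnorm(300), 50, 6)
    yn <- rnorm(50)
    pls_cross_validate(Xn, yn, folds = 5, max_components = 6, seed = sd)$rcv2 <= 0.1
  }, logical(1))
  expect_gte(sum(low), 3)
})

test_that("regression metrics match hand arithmetic", {
  ev <- evaluate_regression(c(0, 1, 2), c(0, 1, 3))
  expect_equal(ev$rmse, sqrt(1 / 3))
  expect_equal(ev$r2, 0.5)
  perfect <- evaluate_regression(1:5, 1:5)
  expect_equal(perfect$r2, 1); expect_equal(perfect$rmse, 0)
  base <- evaluate_regression(c(1, 2, 3), rep(2, 3))
  expect_equal(base$r2, 0)
  expect_warning(ev2 <- evaluate_regression(rep(1, 3), c(1, 1, 2)), "constant")
  expect_true(is.na(ev2$r2))
})
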