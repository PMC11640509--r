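#' Kennard-Stone sample partition
#'
#' Deterministic max-min-distance partition: seed the training set with the
#' two most distant samples (Euclidean), then repeatedly add the sample whose
#' minimum distance to the chosen set is largest. Ties break toward the
#' lowest sample index.
#'
#' @param X Numeric matrix (samples x variables) or [spectra_set()].
#' @param n_train Number of training samples, `2 <= n_train < nrow(X)`.
#' @return List with integer vectors `train` and `test`.
#' @export
kennard_stone_split <- function(X, n_train) {
  X <- as_absorbance(X)
  n <- nrow(X)
  n_train <- assert_count(n_train, "n_train", min = 2L)
  if (n_train >= n) stopf("n_train (%d) must be smaller than the sample count (%d)",
                          n_train, n)
  D <- as.matrix(stats::dist(X))
  # initial pair at maximal distance, lowest indices on ties
  mx <- max(D)
  hit <- which(D == mx, arr.ind = TRUE)
  pair <- sort(unname(hit[order(hit[, 1], hit[, 2])[1], ]))
  sel <- pair
  mind <- pmin(D[, pair[1]], D[, pair[2]])
  mind[sel] <- -Inf
  while (length(sel) < n_train) {
    nxt <- which.max(mind)            # which.max takes the first (lowest index) tie
    sel <- c(sel, nxt)
    mind <- pmin(mind, D[, nxt])
    mind[nxt] <- -Inf
  }
  list(train = sort(sel), test = setdiff(seq_len(n), sel))
}

#' Train/test sizes for the study's 3:1 Kennard-Stone split
#'
#' The training size is computed on the sample total before outlier removal
#' (`round(n_total * ratio / (ratio + 1))`); removed outliers then shrink the
#' test side. With 240 collected fruit and 2 outliers this gives the 180/58
#' partition of the 238 modeled samples.
#'
#' @param n_total Samples collected (before outlier removal).
#' @param n_removed Outliers removed before modeling.
#' @param ratio Training:test ratio (default 3).
#' @return List with `n_train` and `n_test`.
#' @export
ks_split_sizes <- function(n_total, n_removed = 0, ratio = 3) {
  n_total <- assert_count(n_total, "n_total", min = 4L)
  n_removed <- assert_count(n_removed, "n_removed", min = 0L)
  n_train <- as.integer(round(n_total * ratio / (ratio + 1)))
  n_test <- n_total - n_removed - n_train
  if (n_test < 1L) stopf("no test samples left after removal")
  list(n_train = n_train, n_test = n_test)
}

#' Fit a PLS1 regression model (NIPALS)
#'
#' Mean-centered NIPALS partial least squares with a single response.
#' Regression coefficients are accumulated for every component count up to
#' `n_components`, so cross-validated predictions at all model sizes come
#' from one fit.
#'
#' @param X Predictor matrix (samples x variables).
#' @param y Numeric response.
#' @param n_components Number of latent variables, at most
#'   `min(n - 1, p)`.
#' @param scale Autoscale predictors to unit variance before fitting.
#' @return An object of class `pls_model`: centering vectors, weights `W`,
#'   loadings `P`, response loadings `q`, per-size coefficient matrix
#'   `coefficients` (p x A) and intercepts.
#' @export
pls_fit <- function(X, y, n_components, scale = FALSE) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stopf("length(y) != nrow(X)")
  if (sd(y) == 0) stopf("response has zero variance")
  A <- assert_count(n_components, "n_components")
  if (A > min(n - 1L, p))
    stopf("n_components (%d) exceeds min(n - 1, p) = %d", A, min(n - 1L, p))

  x_mean <- colMeans(X); y_mean <- mean(y)
  x_scale <- if (scale) {
    sds <- apply(X, 2, sd); sds[sds == 0] <- 1; sds
  } else rep(1, p)
  Xc <- sweep(sweep(X, 2, x_mean), 2, x_scale, "/")
  yc <- y - y_mean

  W <- matrix(0, p, A); Pl <- matrix(0, p, A); qv <- numeric(A)
  Tm <- matrix(0, n, A)
  for (a in seq_len(A)) {
    w <- crossprod(Xc, yc)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-14) { A <- a - 1L; break }     # residual exhausted
    w <- w / nw
    t <- as.vector(Xc %*% w)
    tt <- sum(t^2)
    pl <- crossprod(Xc, t) / tt
    qa <- sum(yc * t) / tt
    Xc <- Xc - tcrossprod(t, pl)
    yc <- yc - qa * t
    W[, a] <- w; Pl[, a] <- pl; qv[a] <- qa; Tm[, a] <- t
  }
  if (A == 0L) stopf("no usable PLS component (X'y is zero)")
  W <- W[, seq_len(A), drop = FALSE]; Pl <- Pl[, seq_len(A), drop = FALSE]
  qv <- qv[seq_len(A)]; Tm <- Tm[, seq_len(A), drop = FALSE]

  # B_a = W (P'W)^{-1} q for each leading block a; P'W is unit upper triangular
  PtW <- crossprod(Pl, W)
  B <- matrix(0, p, A)
  for (a in seq_len(A)) {
    ra <- seq_len(a)
    B[, a] <- W[, ra, drop = FALSE] %*%
      backsolve(PtW[ra, ra, drop = FALSE], qv[ra])
  }
  B <- B / x_scale
  intercepts <- y_mean - as.vector(crossprod(B, x_mean))

  structure(list(x_mean = x_mean, y_mean = y_mean, x_scale = x_scale,
                 weights = W, x_loadings = Pl, y_loadings = qv,
                 scores = Tm, coefficients = B, intercepts = intercepts,
                 n_components = A, selected = NULL, preprocess = NULL),
            class = "pls_model")
}

#' Predict from a PLS model
#'
#' @param object A [pls_fit()] model.
#' @param newdata Matrix of predictors (same variables as training).
#' @param n_components Model size to predict with (default: all fitted).
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.pls_model <- function(object, newdata, n_components = NULL, ...) {
  a <- n_components %||% object$n_components
  if (a < 1L || a > object$n_components)
    stopf("n_components must be in 1..%d", object$n_components)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$x_mean))
    stopf("newdata has %d variables; model expects %d",
          ncol(newdata), length(object$x_mean))
  as.vector(newdata %*% object$coefficients[, a]) + object$intercepts[a]
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("PLS model: %d components, %d variables\n",
              x$n_components, length(x$x_mean)))
  invisible(x)
}

#' Regression metrics
#'
#' Root mean square error and the coefficient of determination
#' `R2 = 1 - SS_res / SS_tot` (not squared Pearson correlation).
#'
#' @param y_true,y_pred Numeric vectors of equal length (>= 2).
#' @return List with `r2` and `rmse`. `r2` is `NA` (with a warning) when
#'   `y_true` is constant.
#' @export
evaluate_regression <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) stopf("length mismatch")
  if (length(y_true) < 2L) stopf("need at least 2 observations")
  rmse <- sqrt(mean((y_true - y_pred)^2))
  sst <- sum((y_true - mean(y_true))^2)
  if (sst == 0) { warnf("constant y_true: R2 undefined"); r2 <- NA_real_ }
  else r2 <- 1 - sum((y_true - y_pred)^2) / sst
  list(r2 = r2, rmse = rmse)
}

make_folds <- function(n, folds, seed) {
  if (folds < 2L) stopf("folds must be >= 2")
  if (folds > n) stopf("more folds (%d) than samples (%d)", folds, n)
  with_seed(seed, sample(rep_len(seq_len(folds), n)))
}

#' K-fold cross-validation of a PLS model
#'
#' Seeded shuffled fold assignment; out-of-fold predictions are pooled per
#' component count. The chosen size minimizes RMSECV; `Rcv2` is the
#' coefficient of determination of the pooled out-of-fold predictions at that
#' size.
#'
#' @param X Predictor matrix.
#' @param y Response.
#' @param folds Number of folds (default 5).
#' @param max_components Largest model size to consider (default 15, clipped
#'   to the data).
#' @param seed Seed for the fold assignment.
#' @param fold_id Optional explicit fold assignment (overrides `seed`).
#' @return List: `rmsecv` (per component count), `n_components` (RMSECV
#'   minimum), `rcv2`, `rmsecv_min`, `pred` (pooled out-of-fold predictions at
#'   the chosen size), `fold_id`.
#' @export
pls_cross_validate <- function(X, y, folds = 5, max_components = 15, seed = 1,
                               fold_id = NULL) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X)
  fold_id <- fold_id %||% make_folds(n, folds, seed)
  nf <- max(fold_id)
  min_train <- n - max(tabulate(fold_id, nf))
  A <- min(max_components, min_train - 1L, ncol(X))
  if (A < 1L) stopf("not enough samples for cross-validation")
  pred <- matrix(NA_real_, n, A)
  for (f in seq_len(nf)) {
    tr <- fold_id != f
    fit <- pls_fit(X[tr, , drop = FALSE], y[tr], A)
    for (a in seq_len(fit$n_components))
      pred[!tr, a] <- predict(fit, X[!tr, , drop = FALSE], a)
    if (fit$n_components < A)
      pred[!tr, (fit$n_components + 1L):A] <- pred[!tr, fit$n_components]
  }
  rmsecv <- sqrt(colMeans((pred - y)^2))
  a_best <- which.min(rmsecv)
  rcv2 <- evaluate_regression(y, pred[, a_best])$r2
  list(rmsecv = rmsecv, n_components = a_best, rcv2 = rcv2,
       rmsecv_min = rmsecv[a_best], pred = pred[, a_best], fold_id = fold_id)
}
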