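#' CARS configuration
#'
#' Settings for competitive adaptive reweighted sampling: number of
#' Monte-Carlo runs, per-run calibration fraction, cross-validation folds for
#' the RMSECV trace, and the PLS component cap.
#'
#' @param n_runs Monte-Carlo sampling runs (>= 2).
#' @param calib_fraction Fraction of samples drawn per run (0 < f < 1).
#' @param cv_folds Folds for the RMSECV of each retained subset.
#' @param max_components PLS component cap.
#' @param seed Seed driving all CARS randomness.
#' @return An object of class `cars_config`.
#' @export
cars_config <- function(n_runs = 50, calib_fraction = 0.8, cv_folds = 5,
                        max_components = 15, seed = 1) {
  n_runs <- assert_count(n_runs, "n_runs", min = 2L)
  cv_folds <- assert_count(cv_folds, "cv_folds", min = 2L)
  max_components <- assert_count(max_components, "max_components")
  if (calib_fraction <= 0 || calib_fraction >= 1)
    stopf("calib_fraction must be in (0, 1)")
  structure(list(n_runs = n_runs, calib_fraction = calib_fraction,
                 cv_folds = cv_folds, max_components = max_components,
                 seed = assert_count(seed, "seed", min = 0L)),
            class = "cars_config")
}

#' Exponentially decreasing retention ratio
#'
#' Fraction of the `p` initial variables retained at run `i` of `N`:
#' `r_i = a * exp(-k * i)` with the boundary conditions `r_1 = 1` (all
#' variables) and `r_N = 2/p` (two variables), i.e. `k = log(p/2)/(N - 1)`
#' and `a = exp(k)`.
#'
#' @param i Run index (1..N); may be a vector.
#' @param N Total number of runs.
#' @param p Initial variable count (>= 3).
#' @return Retention fraction(s).
#' @export
edf_ratio <- function(i, N, p) {
  N <- assert_count(N, "N", min = 2L)
  p <- assert_count(p, "p", min = 3L)
  if (any(i < 1 | i > N)) stopf("run index out of 1..N")
  k <- log(p / 2) / (N - 1)
  exp(k) * exp(-k * i)
}

#' CARS wavelength selection
#'
#' Competitive adaptive reweighted sampling. Each run draws a Monte-Carlo
#' calibration subset, fits a PLS model on the currently retained variables,
#' and reweights them by the absolute value of their regression coefficients
#' computed on autoscaled variables. The retained set is then reduced to the
#' exponentially decreasing count `round(r_i * p)` by a weighted draw without
#' replacement (weights proportional to |coefficient|), which merges the
#' enforced reduction and the adaptive reweighted sampling into one
#' exact-count step. The RMSECV of every retained subset is measured by
#' k-fold cross-validation on all samples over one fixed seeded fold
#' partition, and the subset with minimal RMSECV wins.
#'
#' @param X Predictor matrix (preprocessed spectra) or [spectra_set()].
#' @param y Response (maturity index values).
#' @param config A [cars_config()].
#' @return An object of class `cars_result`: `selected` (column indices,
#'   sorted), `rmsecv_trace`, `retained_counts`, `best_run`, `n_components`
#'   (CV choice for the winning subset), `subsets` (retained set per run) and
#'   `wavenumbers` of the selection when `X` is a `spectra_set`.
#' @export
cars_select <- function(X, y, config = cars_config()) {
  stopifnot(inherits(config, "cars_config"))
  wn <- if (inherits(X, "spectra_set")) X$wavenumbers else NULL
  X <- as_absorbance(X); y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stopf("length(y) != nrow(X)")
  if (sd(y) == 0) stopf("response has zero variance")
  if (n < config$cv_folds) stopf("fewer samples than cv folds")
  if (p < 3L) stopf("need at least 3 variables")

  N <- config$n_runs
  counts <- as.integer(round(edf_ratio(seq_len(N), N, p) * p))
  counts <- pmax(counts, 2L)
  n_mc <- max(2L, round(config$calib_fraction * n))
  clip_warned <- FALSE

  with_seed(config$seed, {
    fold_id <- sample(rep_len(seq_len(config$cv_folds), n))  # fixed across runs
    retained <- seq_len(p)
    subsets <- vector("list", N)
    rmsecv <- numeric(N)
    ncomp_trace <- integer(N)

    for (i in seq_len(N)) {
      mc <- sample.int(n, n_mc)
      A <- min(config$max_components, length(retained), n_mc - 1L)
      if (A < config$max_components && length(retained) < config$max_components &&
          !clip_warned) {
        warnf("retained variables (%d) fewer than max_components; clipping to %d",
              length(retained), A)
        clip_warned <- TRUE
      }
      fit <- pls_fit(X[mc, retained, drop = FALSE], y[mc], A, scale = TRUE)
      wgt <- abs(fit$coefficients[, fit$n_components] * fit$x_scale)

      k_i <- min(counts[i], length(retained))
      if (k_i < length(retained)) {
        pos <- sum(wgt > 0)
        if (pos >= k_i) {
          pick <- sample(seq_along(retained), k_i, prob = wgt)
        } else {
          # not enough positive weights: rank by weight, lowest index on ties
          pick <- order(-wgt, seq_along(retained))[seq_len(k_i)]
        }
        retained <- sort(retained[pick])
      }
      subsets[[i]] <- retained
      cv <- pls_cross_validate(X[, retained, drop = FALSE], y,
                               max_components = config$max_components,
                               fold_id = fold_id)
      rmsecv[i] <- cv$rmsecv_min
      ncomp_trace[i] <- cv$n_components
    }

    best <- which.min(rmsecv)
    structure(list(selected = subsets[[best]],
                   rmsecv_trace = rmsecv,
                   retained_counts = lengths(subsets),
                   best_run = best,
                   n_components = ncomp_trace[best],
                   subsets = subsets,
                   wavenumbers = if (!is.null(wn)) wn[subsets[[best]]] else NULL),
              class = "cars_result")
  })
}

#' @export
print.cars_result <- function(x, ...) {
  cat(sprintf("CARS selection: %d variables (run %d of %d, RMSECV %.4g)\n",
              length(x$selected), x$best_run, length(x$rmsecv_trace),
              x$rmsecv_trace[x$best_run]))
  invisible(x)
}
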