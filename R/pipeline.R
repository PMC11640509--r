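#' Quantitative CARS-PLS modeling across pretreatments and indices
#'
#' Runs the full quantitative stage for each combination of preprocessing
#' method and maturity index: Kennard-Stone split of the raw spectra,
#' preprocessing fitted on the training set (the MSC reference is the
#' training-set mean), CARS wavelength selection on the training set only,
#' PLS sizing by k-fold RMSECV, and evaluation on the untouched test set.
#'
#' @param spectra A [spectra_set()] (outliers already removed).
#' @param quality Matching quality table.
#' @param methods Preprocessing methods (default all five).
#' @param index_names Maturity indices to model (default all four).
#' @param radar A [radar_spec()]; if unfitted, normalization bounds are
#'   learned from the training fruit.
#' @param cars A [cars_config()].
#' @param n_train Training-set size; default from [ks_split_sizes()] treating
#'   `nrow + n_removed` as the collected total.
#' @param n_removed Outliers removed upstream (affects the default split).
#' @param cv_folds Folds for component selection.
#' @param seed Seed for fold assignment (the split itself is deterministic).
#' @return An object of class `quantitative_result`: `table` (one row per
#'   method x index with PLS factors, variable count, Rcv2, RMSECV, Rp2,
#'   RMSEP), `cells` (per-cell model, selection and wavenumbers), `split`.
#' @export
run_quantitative <- function(spectra, quality,
                             methods = c("sg", "msc", "msc2d", "snv", "snv1d"),
                             index_names = c("streif", "rpi", "iqi", "vrpi"),
                             radar = radar_spec(),
                             cars = cars_config(),
                             n_train = NULL,
                             n_removed = 0,
                             cv_folds = 5,
                             seed = 1) {
  stopifnot(inherits(spectra, "spectra_set"))
  validate_quality(quality)
  if (!identical(spectra$sample_ids, quality$sample_id))
    stopf("spectra and quality sample ids do not match")
  bad <- setdiff(index_names, c("streif", "rpi", "iqi", "vrpi"))
  if (length(bad)) stopf("unknown index: %s", paste(bad, collapse = ", "))

  n <- nrow(spectra$absorbance)
  n_train <- n_train %||% ks_split_sizes(n + n_removed, n_removed)$n_train
  split <- kennard_stone_split(spectra, n_train)

  # radar bounds from the calibration fruit unless already fitted
  if (is.null(radar$bounds))
    radar <- fit_radar_normalizer(quality[split$train, , drop = FALSE], radar)
  idx_tab <- compute_index_table(quality, radar)

  cells <- list()
  rows <- list()
  for (m in methods) {
    spec <- preprocess_spec(m)
    pre_train <- preprocess(spec, spectra[split$train, ])
    ref <- attr(pre_train, "msc_reference")
    pre_test <- preprocess(spec, spectra[split$test, ], reference = ref)
    Xtr <- pre_train$absorbance
    Xte <- pre_test$absorbance
    for (idx in index_names) {
      y_tr <- idx_tab[[idx]][split$train]
      y_te <- idx_tab[[idx]][split$test]
      sel <- cars_select(Xtr, y_tr, cars)
      cv <- pls_cross_validate(Xtr[, sel$selected, drop = FALSE], y_tr,
                               folds = cv_folds,
                               max_components = cars$max_components,
                               seed = seed)
      fit <- pls_fit(Xtr[, sel$selected, drop = FALSE], y_tr, cv$n_components)
      fit$selected <- sel$selected
      fit$selected_wavenumbers <- spectra$wavenumbers[sel$selected]
      fit$preprocess <- m
      fit$msc_reference <- ref
      pred <- predict(fit, Xte[, sel$selected, drop = FALSE])
      ev <- evaluate_regression(y_te, pred)
      key <- paste(m, idx, sep = ".")
      cells[[key]] <- list(model = fit, cars = sel, cv = cv,
                           test_pred = pred, test_obs = y_te)
      rows[[key]] <- data.frame(
        index = idx, pretreatment = preprocess_label(m),
        method = m, pls_factors = cv$n_components,
        variables = length(sel$selected),
        rcv2 = cv$rcv2, rmsecv = cv$rmsecv_min,
        rp2 = ev$r2, rmsep = ev$rmse,
        stringsAsFactors = FALSE
      )
    }
  }
  structure(list(table = do.call(rbind, c(rows, list(make.row.names = FALSE))),
                 cells = cells, split = split, radar = radar,
                 indices = idx_tab),
            class = "quantitative_result")
}

#' @export
print.quantitative_result <- function(x, ...) {
  cat("Quantitative CARS-PLS results\n")
  tab <- x$table
  tab$rcv2 <- round(tab$rcv2, 2); tab$rmsecv <- round(tab$rmsecv, 2)
  tab$rp2 <- round(tab$rp2, 2); tab$rmsep <- round(tab$rmsep, 2)
  print(tab[c("index", "pretreatment", "pls_factors", "variables",
              "rcv2", "rmsecv", "rp2", "rmsep")], row.names = FALSE)
  invisible(x)
}
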