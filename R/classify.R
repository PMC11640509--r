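maturity_classes <- function() c("over-ripe", "ripe", "unripe")

#' Post-ripening batch scores
#'
#' Min-max-normalizes the five post-ripening quality parameters over the
#' batches (a*, SSC and edible rate forward; TA and rot rate reverse) and
#' assigns each an equal weight of 0.2; the batch score is the weighted sum,
#' i.e. the mean of the five normalized values.
#'
#' @param x A [simulate_postripening()] table of raw per-batch values, or an
#'   already normalized, direction-adjusted table if `normalized = TRUE`.
#'   Needs columns `a`, `ssc`, `ta`, `edible_rate`, `rot_rate` (and `daf`).
#' @param normalized Set to `TRUE` when `x` already holds normalized values.
#' @return Data frame with `daf`, the five normalized values and `score`.
#' @export
post_ripeness_score <- function(x, normalized = FALSE) {
  cols <- c("a", "ssc", "ta", "edible_rate", "rot_rate")
  if (!all(cols %in% names(x)))
    stopf("missing column %s", setdiff(cols, names(x))[1])
  if (nrow(x) < 2L && !normalized)
    stopf("need at least 2 batches to normalize")
  out <- data.frame(daf = x$daf %||% seq_len(nrow(x)))
  reverse <- c(a = FALSE, ssc = FALSE, ta = TRUE, edible_rate = FALSE,
               rot_rate = TRUE)
  for (colname in cols) {
    v <- x[[colname]]
    if (!normalized) {
      r <- range(v)
      if (r[1] == r[2]) stopf("constant column %s: normalization undefined", colname)
      v <- (v - r[1]) / (r[2] - r[1])
      if (reverse[[colname]]) v <- 1 - v
    }
    out[[colname]] <- v
  }
  out$score <- 0.2 * rowSums(out[cols])
  out
}

#' Fruit scores and maturity labels
#'
#' Min-max-normalizes each fruit's VRPI over the fruit set (values outside
#' supplied bounds are clipped to `[0, 1]` with a warning), adds the
#' post-ripening score of the fruit's batch, and labels the fruit by the
#' resulting score `Fs`: unripe for `Fs < 0.8`, ripe for `0.8 <= Fs < 1.2`,
#' over-ripe for `Fs >= 1.2`.
#'
#' @param vrpi Per-fruit VRPI values.
#' @param daf Per-fruit batch label (days after flowering).
#' @param batch_scores Data frame from [post_ripeness_score()] (columns `daf`,
#'   `score`).
#' @param bounds Optional VRPI normalization bounds `c(min, max)`; default is
#'   the range of `vrpi`.
#' @return Data frame with `daf`, `vrpi_norm`, `post_score`, `fs` and `label`
#'   (factor with levels over-ripe, ripe, unripe).
#' @export
fruit_scores <- function(vrpi, daf, batch_scores, bounds = NULL) {
  if (length(vrpi) != length(daf)) stopf("vrpi and daf lengths differ")
  if (!all(daf %in% batch_scores$daf))
    stopf("missing post-ripening score for batch(es): %s",
          paste(setdiff(unique(daf), batch_scores$daf), collapse = ", "))
  bounds <- bounds %||% range(vrpi)
  if (bounds[1] >= bounds[2]) stopf("invalid vrpi bounds")
  vn <- (vrpi - bounds[1]) / (bounds[2] - bounds[1])
  if (any(vn < 0 | vn > 1)) {
    warnf("%d VRPI value(s) outside bounds; clipped to [0, 1]", sum(vn < 0 | vn > 1))
    vn <- pmin(1, pmax(0, vn))
  }
  ps <- batch_scores$score[match(daf, batch_scores$daf)]
  fs <- vn + ps
  label <- cut(fs, breaks = c(-Inf, 0.8, 1.2, Inf),
               labels = c("unripe", "ripe", "over-ripe"), right = FALSE)
  data.frame(daf = daf, vrpi_norm = vn, post_score = ps, fs = fs,
             label = factor(label, levels = maturity_classes()))
}

#' Classifier specification
#'
#' The five classification algorithms with their fixed hyperparameters:
#' linear discriminant analysis with cross-validated covariance shrinkage
#' (LDA); naive Bayes with per-class per-feature
#' Gaussian kernel density estimates (NB); k-nearest neighbours with k = 3,
#' cubic Minkowski distance and inverse-squared-distance weights (KNN);
#' linear support vector machine with box constraint 0.5901 and one-vs-one
#' multiclass coding (SVM); single-hidden-layer neural network with 50
#' sigmoid neurons, 200 iterations and L2 regularization 0.00030942 (NN).
#' All classifiers standardize features using training-data statistics only.
#'
#' @param algo One of `"lda"`, `"nb"`, `"knn"`, `"svm"`, `"nn"`.
#' @param ... Hyperparameter overrides (`k`, `minkowski_p`, `cost`,
#'   `hidden`, `maxit`, `decay`).
#' @return An object of class `classifier_spec`.
#' @export
classifier_spec <- function(algo = c("lda", "nb", "knn", "svm", "nn"), ...) {
  algo <- match.arg(algo)
  defaults <- switch(algo,
    lda = list(),
    nb = list(),
    knn = list(k = 3L, minkowski_p = 3),
    svm = list(cost = 0.5901),
    nn = list(hidden = 50L, maxit = 200L, decay = 0.00030942)
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown)) stopf("unknown hyperparameter(s) for %s: %s",
                             algo, paste(unknown, collapse = ", "))
  defaults[names(over)] <- over
  structure(c(list(algo = algo), defaults), class = "classifier_spec")
}

standardize_fit <- function(X) {
  ctr <- colMeans(X)
  scl <- apply(X, 2, sd)
  scl[scl == 0] <- 1
  list(center = ctr, scale = scl)
}

standardize_apply <- function(X, st) {
  sweep(sweep(X, 2, st$center), 2, st$scale, "/")
}

#' Train a maturity classifier
#'
#' Fits the classifier of `spec` on standardized features; the
#' standardization statistics come from the training data only and are
#' stored with the model.
#'
#' @param X Feature matrix (samples x selected wavelengths).
#' @param labels Factor (or character) of class labels; at least two classes.
#' @param spec A [classifier_spec()].
#' @param seed Seed (used by the NN weight initialization).
#' @return An object of class `nirpear_classifier`.
#' @export
train_classifier <- function(X, labels, spec, seed = 1) {
  stopifnot(inherits(spec, "classifier_spec"))
  X <- as_absorbance(X)
  labels <- if (is.factor(labels)) droplevels(labels) else factor(labels)
  if (nlevels(labels) < 2L) stopf("need at least 2 classes in training data")
  if (any(tabulate(labels) == 0L)) {
    miss <- levels(labels)[tabulate(labels) == 0L]
    stopf("class absent from training data: %s", paste(miss, collapse = ", "))
  }
  st <- standardize_fit(X)
  Z <- standardize_apply(X, st)

  fit <- switch(spec$algo,
    lda = rlda_fit(Z, labels, seed = seed),
    svm = e1071::svm(Z, labels, kernel = "linear", cost = spec$cost,
                     scale = FALSE),
    nn = nn_fit(Z, labels, hidden = spec$hidden, decay = spec$decay,
                maxit = spec$maxit, seed = seed),
    knn = list(Z = Z, labels = labels),
    nb = kde_nb_fit(Z, labels)
  )
  structure(list(algo = spec$algo, spec = spec, fit = fit,
                 standardize = st, levels = levels(labels)),
            class = "nirpear_classifier")
}

# Regularized linear discriminant: pooled within-class covariance shrunk
# toward a scaled identity, S_g = (1 - g) S + g (tr S / p) I. The shrinkage
# intensity is chosen by seeded internal cross-validation on the training
# data, which keeps the discriminant stable when the selected wavelengths
# are strongly collinear.
rlda_fit <- function(Z, labels, seed = 1,
                     gammas = c(0.01, 0.05, 0.1, 0.25, 0.5, 0.75)) {
  build <- function(Z, labels, gamma) {
    classes <- levels(labels)
    p <- ncol(Z)
    M <- t(vapply(classes, function(cl)
      colMeans(Z[labels == cl, , drop = FALSE]), numeric(p)))
    Sw <- matrix(0, p, p)
    for (k in seq_along(classes)) {
      Zi <- sweep(Z[labels == classes[k], , drop = FALSE], 2, M[k, ])
      Sw <- Sw + crossprod(Zi)
    }
    Sw <- Sw / (nrow(Z) - length(classes))
    Sg <- (1 - gamma) * Sw + gamma * (sum(diag(Sw)) / p) * diag(p)
    W <- tryCatch(solve(Sg, t(M)), error = function(e) NULL)  # p x K
    if (is.null(W)) return(NULL)
    prior <- as.vector(table(labels)) / length(labels)
    const <- -0.5 * colSums(t(M) * W) + log(prior)
    list(W = W, const = const, classes = classes, gamma = gamma)
  }
  score <- function(model, Z) {
    S <- Z %*% model$W + rep(model$const, each = nrow(Z))
    model$classes[max.col(S, ties.method = "first")]
  }
  acc <- vapply(gammas, function(g) {
    fold_id <- with_seed(seed, sample(rep_len(1:5, nrow(Z))))
    ok <- 0L; tot <- 0L
    for (f in 1:5) {
      tr <- fold_id != f
      if (nlevels(droplevels(labels[tr])) < nlevels(labels)) return(NA_real_)
      m <- build(Z[tr, , drop = FALSE], labels[tr], g)
      if (is.null(m)) return(NA_real_)
      pr <- score(m, Z[!tr, , drop = FALSE])
      ok <- ok + sum(pr == as.character(labels[!tr])); tot <- tot + sum(!tr)
    }
    ok / tot
  }, numeric(1))
  g_best <- gammas[which.max(acc)]
  model <- build(Z, labels, g_best)
  if (is.null(model)) model <- build(Z, labels, max(gammas))
  model$score <- score
  model
}

# Single-hidden-layer softmax network: sigmoid hidden units, cross-entropy
# loss with L2 penalty on the weights, trained by L-BFGS with analytic
# gradients (the limited-memory optimizer keeps training fast at the
# 50-neuron x few-hundred-wavelength scale).
nn_fit <- function(Z, labels, hidden, decay, maxit, seed) {
  n <- nrow(Z); p <- ncol(Z)
  classes <- levels(labels)
  K <- length(classes)
  Y <- diag(K)[as.integer(labels), , drop = FALSE]
  sizes <- c(p * hidden, hidden, hidden * K, K)
  unpack <- function(th) {
    o <- cumsum(sizes)
    list(W1 = matrix(th[1:o[1]], p, hidden),
         b1 = th[(o[1] + 1):o[2]],
         W2 = matrix(th[(o[2] + 1):o[3]], hidden, K),
         b2 = th[(o[3] + 1):o[4]])
  }
  forward <- function(w) {
    A1 <- 1 / (1 + exp(-(Z %*% w$W1 + rep(w$b1, each = n))))
    S <- A1 %*% w$W2 + rep(w$b2, each = n)
    S <- S - apply(S, 1, max)
    E <- exp(S)
    list(A1 = A1, P = E / rowSums(E))
  }
  fn <- function(th) {
    w <- unpack(th); f <- forward(w)
    -sum(Y * log(pmax(f$P, 1e-300))) +
      decay * (sum(w$W1^2) + sum(w$W2^2))
  }
  gr <- function(th) {
    w <- unpack(th); f <- forward(w)
    dS <- f$P - Y                              # n x K
    gW2 <- crossprod(f$A1, dS) + 2 * decay * w$W2
    gb2 <- colSums(dS)
    dA1 <- dS %*% t(w$W2) * f$A1 * (1 - f$A1)  # n x hidden
    gW1 <- crossprod(Z, dA1) + 2 * decay * w$W1
    gb1 <- colSums(dA1)
    c(gW1, gb1, gW2, gb2)
  }
  th0 <- with_seed(seed, runif(sum(sizes), -0.5, 0.5) / sqrt(p))
  opt <- stats::optim(th0, fn, gr, method = "L-BFGS-B",
                      control = list(maxit = maxit))
  list(weights = unpack(opt$par), classes = classes, value = opt$value)
}

nn_predict <- function(fit, Z) {
  w <- fit$weights
  A1 <- 1 / (1 + exp(-(Z %*% w$W1 + rep(w$b1, each = nrow(Z)))))
  S <- A1 %*% w$W2 + rep(w$b2, each = nrow(Z))
  fit$classes[max.col(S, ties.method = "first")]
}

# Gaussian kernel density naive Bayes: per class and feature, the class
# density is a kernel estimate with normal-reference bandwidth.
kde_nb_fit <- function(Z, labels) {
  classes <- levels(labels)
  models <- lapply(classes, function(cl) {
    Zi <- Z[labels == cl, , drop = FALSE]
    bw <- apply(Zi, 2, function(x) {
      b <- stats::bw.nrd0(x)
      if (!is.finite(b) || b <= 0) b <- max(1e-3, sd(x) / 2, na.rm = TRUE)
      b
    })
    list(Z = Zi, bw = bw, prior = nrow(Zi))
  })
  names(models) <- classes
  total <- sum(vapply(models, `[[`, numeric(1), "prior"))
  for (cl in classes) models[[cl]]$prior <- models[[cl]]$prior / total
  models
}

kde_nb_predict <- function(models, Z) {
  classes <- names(models)
  ll <- vapply(classes, function(cl) {
    m <- models[[cl]]
    s <- log(m$prior) + numeric(nrow(Z))
    for (j in seq_len(ncol(Z))) {
      d <- outer(Z[, j], m$Z[, j], "-") / m$bw[j]
      dens <- rowMeans(dnorm(d)) / m$bw[j]
      s <- s + log(pmax(dens, 1e-300))
    }
    s
  }, numeric(nrow(Z)))
  classes[max.col(ll, ties.method = "first")]
}

knn_predict <- function(fit, Z, k, pw, levels) {
  pred <- character(nrow(Z))
  for (i in seq_len(nrow(Z))) {
    d <- (rowSums(abs(sweep(fit$Z, 2, Z[i, ]))^pw))^(1 / pw)
    o <- order(d, seq_along(d))[seq_len(k)]
    w <- 1 / pmax(d[o], 1e-12)^2      # inverse squared distance
    votes <- tapply(w, fit$labels[o], sum, default = 0)
    pred[i] <- names(votes)[which.max(votes)]
  }
  pred
}

#' Predict maturity classes
#'
#' @param object A [train_classifier()] model.
#' @param newdata Feature matrix with the training variables.
#' @param ... Unused.
#' @return Factor of predicted labels.
#' @export
predict.nirpear_classifier <- function(object, newdata, ...) {
  Z <- standardize_apply(as_absorbance(newdata), object$standardize)
  pred <- switch(object$algo,
    lda = object$fit$score(object$fit, Z),
    svm = as.character(predict(object$fit, Z)),
    nn = nn_predict(object$fit, Z),
    knn = knn_predict(object$fit, Z, object$spec$k, object$spec$minkowski_p,
                      object$levels),
    nb = kde_nb_predict(object$fit, Z)
  )
  factor(pred, levels = object$levels)
}

#' Confusion matrix and classification accuracy
#'
#' @param actual,predicted Label vectors.
#' @param classes Class order for the matrix rows/columns (default the
#'   over-ripe / ripe / unripe order).
#' @return An object of class `class_report`: `confusion` (rows = actual),
#'   `ca` (percent, full precision) and `ca_reported` (one decimal).
#' @export
class_report <- function(actual, predicted, classes = maturity_classes()) {
  actual <- factor(as.character(actual), levels = classes)
  predicted <- factor(as.character(predicted), levels = classes)
  if (anyNA(actual) || anyNA(predicted)) stopf("labels outside the class set")
  cm <- table(actual = actual, predicted = predicted)
  ca <- confusion_accuracy(cm)
  structure(list(confusion = unclass(cm), ca = ca,
                 ca_reported = round(ca, 1), n = length(actual)),
            class = "class_report")
}

#' Classification accuracy from a confusion matrix
#'
#' `100 * trace / total`, the percentage of correctly classified samples.
#'
#' @param confusion Square confusion matrix (rows = actual).
#' @return Accuracy in percent.
#' @export
confusion_accuracy <- function(confusion) {
  confusion <- as.matrix(confusion)
  if (nrow(confusion) != ncol(confusion)) stopf("confusion matrix must be square")
  100 * sum(diag(confusion)) / sum(confusion)
}

#' @export
print.class_report <- function(x, ...) {
  cat(sprintf("Classification accuracy: %.1f%% (n = %d)\n", x$ca, x$n))
  print(x$confusion)
  invisible(x)
}

#' Evaluate a classifier by cross-validation or holdout
#'
#' `"cv"` uses seeded shuffled k-fold cross-validation and pools the
#' out-of-fold predictions. `"holdout"` splits by Kennard-Stone on the
#' features (default calibration size `ceiling(3n/4)`, e.g. 179/59 for 238
#' fruit) and evaluates on the held-out side. Standardization (and the
#' classifier itself) never sees the evaluation samples.
#'
#' @param X Feature matrix.
#' @param labels Class labels.
#' @param spec A [classifier_spec()].
#' @param validation `"cv"` or `"holdout"`.
#' @param folds Folds for `"cv"` (default 5).
#' @param n_train Calibration size for `"holdout"`.
#' @param seed Seed for fold assignment / NN initialization.
#' @return A [class_report()] with the validation mode and algorithm attached.
#' @export
evaluate_classifier <- function(X, labels, spec, validation = c("cv", "holdout"),
                                folds = 5, n_train = NULL, seed = 1) {
  validation <- match.arg(validation)
  X <- as_absorbance(X)
  labels <- factor(as.character(labels), levels = maturity_classes())
  n <- nrow(X)
  if (validation == "cv") {
    fold_id <- make_folds(n, folds, seed)
    pred <- factor(rep(NA_character_, n), levels = maturity_classes())
    for (f in seq_len(max(fold_id))) {
      tr <- fold_id != f
      model <- train_classifier(X[tr, , drop = FALSE], labels[tr], spec,
                                seed = seed + f)
      pred[!tr] <- predict(model, X[!tr, , drop = FALSE])
    }
    rep_ <- class_report(labels, pred)
  } else {
    n_train <- n_train %||% as.integer(ceiling(3 * n / 4))
    split <- kennard_stone_split(X, n_train)
    if (length(split$test) < 1L) stopf("empty test set")
    model <- train_classifier(X[split$train, , drop = FALSE],
                              labels[split$train], spec, seed = seed)
    pred <- predict(model, X[split$test, , drop = FALSE])
    rep_ <- class_report(labels[split$test], pred)
  }
  rep_$validation <- validation
  rep_$algo <- spec$algo
  rep_
}

#' Qualitative classification stage across pretreatments
#'
#' For each preprocessing method (default the two best quantitative
#' pretreatments), classifies the fruit from the CARS-selected wavelengths of
#' the preprocessed spectra with every requested algorithm under both
#' validation modes.
#'
#' @param spectra Raw [spectra_set()] (outliers removed).
#' @param labels Per-fruit maturity labels (see [fruit_scores()]).
#' @param selected Named list: per preprocessing method, the selected column
#'   indices (e.g. from the quantitative stage's `cells`).
#' @param algos Algorithms to run (default all five).
#' @param validations Validation modes (default both).
#' @param folds,seed Passed to [evaluate_classifier()].
#' @return Data frame with one row per method x algorithm x validation
#'   (columns `method`, `algo`, `validation`, `ca`, `ca_reported`) and the
#'   full reports in attribute `reports`.
#' @export
run_qualitative <- function(spectra, labels, selected,
                            algos = c("svm", "knn", "nn", "nb", "lda"),
                            validations = c("cv", "holdout"),
                            folds = 5, seed = 1) {
  stopifnot(inherits(spectra, "spectra_set"))
  reports <- list()
  rows <- list()
  for (m in names(selected)) {
    pre <- preprocess(preprocess_spec(m), spectra)
    Xm <- pre$absorbance[, selected[[m]], drop = FALSE]
    for (algo in algos) {
      spec <- classifier_spec(algo)
      for (v in validations) {
        rep_ <- evaluate_classifier(Xm, labels, spec, validation = v,
                                    folds = folds, seed = seed)
        key <- paste(m, algo, v, sep = ".")
        reports[[key]] <- rep_
        rows[[key]] <- data.frame(method = m, algo = algo, validation = v,
                                  ca = rep_$ca, ca_reported = rep_$ca_reported,
                                  stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  attr(out, "reports") <- reports
  out
}
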