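test_that("post-ripening scores are the mean of the normalized values", {
  ref <- reference_postripening()
  sc <- post_ripeness_score(ref, normalized = TRUE)
  expect_equal(round(sc$score, 2), c(0.07, 0.44, 0.84, 0.74))
  expect_equal(sc$score[1], 0.2 * 0.37)
  zero <- post_ripeness_score(
    data.frame(daf = 1, a = 0, ssc = 0, ta = 0, edible_rate = 0, rot_rate = 0),
    normalized = TRUE)
  expect_equal(zero$score, 0)
  expect_error(post_ripeness_score(data.frame(a = 1:2, ssc = 1:2, ta = 1:2,
                                              edible_rate = 1:2)),
               "missing column")
  one_batch <- data.frame(daf = 1, a = 1, ssc = 1, ta = 1,
                          edible_rate = 50, rot_rate = 5)
  expect_error(post_ripeness_score(one_batch), "at least 2 batches")
})

test_that("fruit score thresholds label exactly as printed", {
  bs <- data.frame(daf = c(1, 2, 3, 4, 5, 6),
                   score = c(0.5, 1.0, 1.3, 0.8, 1.2, 0))
  fs <- fruit_scores(rep(0, 6), 1:6, bs, bounds = c(0, 1))
  expect_equal(as.character(fs$label),
               c("unripe", "ripe", "over-ripe", "ripe", "over-ripe", "unripe"))
  expect_equal(fs$fs, bs$score)
  # vrpi at the lower bound with zero batch score -> Fs = 0 -> unripe
  expect_equal(as.character(fs$label[6]), "unripe")
  # clipping outside bounds warns
  expect_warning(fruit_scores(c(-0.5, 2), c(1, 1), bs, bounds = c(0, 1)),
                 "clipped")
  # label is a pure step function of Fs (batch score shifts the grid so both
  # thresholds are crossed while vrpi_norm stays inside [0, 1])
  grid <- seq(0, 1, by = 0.005)
  lab <- fruit_scores(grid, rep(1, length(grid)),
                      data.frame(daf = 1, score = 0.5), bounds = c(0, 1))
  expect_equal(as.character(lab$label),
               ifelse(lab$fs < 0.8, "unripe",
                      ifelse(lab$fs < 1.2, "ripe", "over-ripe")))
})

test_that("confusion matrices and accuracies follow trace/total", {
  pred <- factor(c("over-ripe", "ripe", "ripe", "unripe"),
                 levels = maturity_levels <- c("over-ripe", "ripe", "unripe"))
  act <- factor(c("over-ripe", "over-ripe", "ripe", "unripe"),
                levels = maturity_levels)
  rep_ <- class_report(act, pred)
  expect_equal(sum(rep_$confusion), 4)
  expect_equal(unname(rowSums(rep_$confusion)), c(2, 1, 1))
  expect_equal(rep_$ca, 75)
  # printed-table arithmetic
  cm <- diag(c(39, 52, 120)); cm[1, 2] <- 12; cm[2, 1] <- 15
  expect_equal(round(confusion_accuracy(cm), 1), 88.7)
  cm2 <- diag(c(10, 13, 31)); cm2[1, 2] <- 2; cm2[2, 1] <- 3
  expect_equal(round(confusion_accuracy(cm2), 1), 91.5)
  expect_equal(confusion_accuracy(diag(c(5, 5, 5))), 100)
})

two_gaussians <- function(seed, n = 60, p = 6, sep = 4) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n / 2 * p), ncol = p),
             matrix(rnorm(n / 2 * p, mean = sep), ncol = p))
  labels <- factor(rep(c("unripe", "ripe"), each = n / 2),
                   levels = c("over-ripe", "ripe", "unripe"))
  list(X = X, labels = labels)
}

test_that("all five classifiers separate well-separated Gaussian classes", {
  for (algo in c("lda", "nb", "knn", "svm", "nn")) {
    ok <- vapply(1:5, function(sd) {
      d <- two_gaussians(sd)
      rep_ <- evaluate_classifier(d$X, d$labels, classifier_spec(algo),
                                  validation = "cv", seed = sd)
      rep_$ca >= 95
    }, logical(1))
    expect_gte(sum(ok), 3)
  }
})

test_that("KNN predicts a training point's own class and permuted labels have no skill", {
  d <- two_gaussians(1)
  model <- train_classifier(d$X, d$labels, classifier_spec("knn"))
  expect_equal(as.character(predict(model, d$X[1, , drop = FALSE])),
               as.character(d$labels[1]))
  # label permutation null: CV accuracy near chance (1/2 here, 2 classes)
  cas <- vapply(1:5, function(sd) {
    d <- two_gaussians(sd, n = 90)
    perm <- with_seed_test(sd, sample(seq_along(d$labels)))
    evaluate_classifier(d$X, d$labels[perm], classifier_spec("knn"),
                        validation = "cv", seed = sd)$ca
  }, numeric(1))
  expect_gte(sum(abs(cas - 50) <= 12), 3)
})

test_that("classifier training validates inputs and freezes standardization", {
  d <- two_gaussians(2)
  expect_error(train_classifier(d$X, rep("ripe", nrow(d$X)),
                                classifier_spec("svm")), "2 classes")
  model <- train_classifier(d$X, d$labels, classifier_spec("svm"))
  expect_equal(model$standardize$center, colMeans(d$X))
  # prediction uses the training standardization, not the test batch's
  shifted <- d$X + 100
  expect_false(all(predict(model, shifted) == predict(model, d$X)))
})

test_that("holdout evaluation uses the ceiling 3:1 split (179/59 for 238 fruit)", {
  set.seed(11)
  X <- matrix(rnorm(238 * 4), 238, 4)
  labels <- factor(rep(c("over-ripe", "ripe", "unripe"), length.out = 238),
                   levels = c("over-ripe", "ripe", "unripe"))
  rep_ <- evaluate_classifier(X, labels, classifier_spec("knn"),
                              validation = "holdout", seed = 1)
  expect_equal(rep_$n, 59L)
  expect_equal(sum(rep_$confusion), 59)
})
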