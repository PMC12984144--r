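# Metrics suite: confusion counts, derived metrics, ROC/AUC, CV pooling.

test_that("confusion counts match direct tallies and validate inputs", {
  cm <- confusion(c(1, 1, 0, 0), c(1, 0, 0, 1))
  expect_equal(unclass(cm)[c("tp", "fn", "tn", "fp")],
               list(tp = 1L, fn = 1L, tn = 1L, fp = 1L), ignore_attr = TRUE)
  perfect <- confusion(c(1, 0, 1), c(1, 0, 1))
  expect_equal(perfect$fp + perfect$fn, 0L)
  set.seed(61)
  labels <- rbinom(200, 1, 0.4)
  preds <- rbinom(200, 1, 0.5)
  expect_equal(unclass(confusion(labels, preds))[c("tp", "fp", "fn", "tn")],
               oracle_confusion(labels, preds), ignore_attr = TRUE)
  expect_error(confusion(c(1, 0), c(1)), "length")
  expect_error(confusion(c(1, 2), c(1, 0)), "binary")
})

test_that("metrics agree with hand-computed values", {
  # 3/1/2/4 case: all formulas evaluated by hand
  m <- binary_metrics(list(tp = 3, fp = 1, fn = 2, tn = 4))
  expect_equal(m$accuracy, 0.7)
  expect_equal(m$sensitivity, 0.6)
  expect_equal(m$specificity, 0.8)
  expect_equal(m$f1, 2 * 0.75 * 0.6 / 1.35, tolerance = 1e-12)
  expect_equal(m$kappa, 0.4)
  perfect <- binary_metrics(list(tp = 5, fp = 0, fn = 0, tn = 5))
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$kappa, 1)
})

test_that("published error counts reproduce the reported accuracies to 4 decimals", {
  # 991 test images, 42 false negatives + 18 false positives
  m1 <- binary_metrics(list(tp = 200, fn = 42, fp = 18, tn = 731))
  expect_equal(m1$accuracy, 0.9394, tolerance = 1e-4)
  # 49 false negatives + 23 false positives
  m2 <- binary_metrics(list(tp = 193, fn = 49, fp = 23, tn = 726))
  expect_equal(m2$accuracy, 0.9273, tolerance = 1e-4)
})

test_that("undefined ratios are NA, never zero", {
  m <- binary_metrics(list(tp = 0, fp = 0, fn = 0, tn = 10))
  expect_true(is.na(m$sensitivity))
  expect_true(is.na(m$precision))
  expect_equal(m$specificity, 1)
})

test_that("kappa vanishes for label-independent predictions", {
  # marginals match but predictions carry no information
  m <- binary_metrics(list(tp = 20, fp = 20, fn = 30, tn = 30))
  expect_equal(m$kappa, 0)
})

test_that("AUC handles separations, ties and the worked 4-sample case", {
  expect_equal(roc_auc(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1))$auc, 1)
  expect_equal(roc_auc(c(1, 0, 1, 0), c(0.5, 0.5, 0.5, 0.5))$auc, 0.5)
  # brute force over the 4 positive-negative pairs gives 3/4
  expect_equal(roc_auc(c(1, 0, 1, 0), c(0.9, 0.8, 0.4, 0.3))$auc, 0.75)
  expect_error(roc_auc(c(1, 1), c(0.2, 0.3)), "single class")
})

test_that("AUC and metrics match brute-force oracles on random instances", {
  set.seed(62)
  for (i in 1:200) {
    n <- sample(8:25, 1)
    labels <- c(0, 1, rbinom(n - 2, 1, runif(1, 0.2, 0.8)))
    scores <- round(runif(n), sample(c(1, 2, 6), 1))  # induces ties sometimes
    expect_equal(roc_auc(labels, scores)$auc, oracle_auc(labels, scores),
                 tolerance = 1e-9)
    preds <- as.integer(scores > 0.5)
    oc <- oracle_confusion(labels, preds)
    m <- binary_metrics(confusion(labels, preds))
    expect_equal(m$accuracy, mean(labels == preds), tolerance = 1e-9)
    if (sum(preds) > 0 && sum(labels) > 0) {
      expect_equal(m$sensitivity, oc$tp / (oc$tp + oc$fn), tolerance = 1e-9)
    }
  }
})

test_that("trapezoidal area under the returned curve equals the rank AUC", {
  set.seed(63)
  labels <- rbinom(60, 1, 0.5)
  labels[1:2] <- 0:1
  scores <- rnorm(60)  # no ties almost surely
  r <- roc_auc(labels, scores)
  trap <- sum(diff(r$curve$fpr) * (head(r$curve$tpr, -1) + r$curve$tpr[-1]) / 2)
  expect_equal(trap, r$auc, tolerance = 1e-9)
})

test_that("cross-validation pooling sums counts and concatenates scores", {
  set.seed(64)
  folds <- lapply(1:5, function(i) {
    labels <- c(0, 1, rbinom(38, 1, 0.5))
    list(labels = labels, scores = runif(40))
  })
  agg <- aggregate_cv(folds)
  all_labels <- unlist(lapply(folds, `[[`, "labels"))
  all_scores <- unlist(lapply(folds, `[[`, "scores"))
  expect_equal(agg$pooled$accuracy,
               mean(all_labels == (all_scores > 0.5)), tolerance = 1e-12)
  expect_equal(agg$pooled$auc, oracle_auc(all_labels, all_scores),
               tolerance = 1e-9)
  # five identical folds pool to any single fold
  same <- aggregate_cv(rep(folds[1], 5))
  one <- binary_metrics(confusion(folds[[1]]$labels,
                                  as.integer(folds[[1]]$scores > 0.5)))
  expect_equal(same$pooled$accuracy, one$accuracy)
  expect_error(aggregate_cv(list()), "no fold")
})

test_that("AUC agrees with pROC as an independent reference", {
  skip_if_not_installed("pROC")
  set.seed(65)
  labels <- c(0, 1, rbinom(98, 1, 0.45))
  scores <- runif(100)
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(roc_auc(labels, scores)$auc, ref, tolerance = 1e-9)
})
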