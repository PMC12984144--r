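# Binary classification metrics with glaucoma (label 1) as the positive
# class: confusion counts, accuracy, sensitivity (glaucoma recall),
# specificity (normal recall), F1, Cohen's kappa, ROC/AUC, and pooling
# across cross-validation folds.

#' Confusion matrix of binary predictions
#'
#' @param labels true labels, 0 (normal) / 1 (glaucoma).
#' @param predicted predicted labels, same coding and length.
#' @return an object of class `confusion_matrix` with integer counts
#'   `tp`, `fp`, `fn`, `tn` (glaucoma positive).
#' @export
confusion <- function(labels, predicted) {
  if (length(labels) != length(predicted)) {
    stopf("labels and predictions differ in length (%d vs %d)",
          length(labels), length(predicted))
  }
  if (!all(labels %in% c(0, 1)) || !all(predicted %in% c(0, 1))) {
    stopf("labels and predictions must be binary 0/1")
  }
  structure(list(tp = sum(labels == 1 & predicted == 1),
                 fp = sum(labels == 0 & predicted == 1),
                 fn = sum(labels == 1 & predicted == 0),
                 tn = sum(labels == 0 & predicted == 0)),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(truth = c("glaucoma", "normal"),
                              predicted = c("glaucoma", "normal")))
  print(m)
  invisible(x)
}

#' Metrics from a confusion matrix
#'
#' Accuracy, sensitivity `tp/(tp+fn)`, specificity `tn/(tn+fp)`, precision,
#' F1 for the glaucoma class (harmonic mean of precision and sensitivity),
#' F1 for the normal class, and unweighted Cohen's kappa. Any ratio with a
#' zero denominator is reported as `NA`, never as 0.
#'
#' @param cm a [confusion()] object (or a list with `tp`, `fp`, `fn`, `tn`).
#' @return a list of class `metrics_report`.
#' @export
binary_metrics <- function(cm) {
  tp <- cm$tp; fp <- cm$fp; fn <- cm$fn; tn <- cm$tn
  total <- tp + fp + fn + tn
  if (total < 1) stopf("confusion matrix is empty")
  safe_div <- function(a, b) if (b == 0) NA_real_ else a / b
  sens <- safe_div(tp, tp + fn)
  spec <- safe_div(tn, tn + fp)
  prec <- safe_div(tp, tp + fp)
  f1 <- if (is.na(prec) || is.na(sens) || (prec + sens) == 0) NA_real_
        else 2 * prec * sens / (prec + sens)
  npv <- safe_div(tn, tn + fn)
  f1_neg <- if (is.na(npv) || is.na(spec) || (npv + spec) == 0) NA_real_
            else 2 * npv * spec / (npv + spec)
  po <- (tp + tn) / total
  pe <- ((tp + fp) * (tp + fn) + (fn + tn) * (fp + tn)) / total^2
  kappa <- if (pe == 1) NA_real_ else (po - pe) / (1 - pe)
  structure(list(accuracy = po, sensitivity = sens, specificity = spec,
                 precision = prec, f1 = f1, f1_negative = f1_neg,
                 kappa = kappa, total = total,
                 cm = list(tp = tp, fp = fp, fn = fn, tn = tn)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "accuracy %.4f | sensitivity %s | specificity %s | F1 %s | kappa %s%s\n",
    x$accuracy, fmtna(x$sensitivity), fmtna(x$specificity), fmtna(x$f1),
    fmtna(x$kappa),
    if (!is.null(x$auc)) sprintf(" | AUC %.4f", x$auc) else ""))
  invisible(x)
}

fmtna <- function(v) if (is.na(v)) "NA" else sprintf("%.4f", v)

#' ROC curve and AUC
#'
#' AUC equals the probability that a random glaucoma case outscores a random
#' normal case, with ties counting one half (the Mann-Whitney statistic);
#' the curve lists (FPR, TPR) at every distinct score threshold.
#'
#' @param labels true labels, 0/1, with both classes present.
#' @param scores predicted probability (or any monotone score) of the
#'   glaucoma class.
#' @return a list with `auc` and `curve` (data frame `threshold`, `fpr`,
#'   `tpr`, sorted from the strictest threshold down).
#' @export
roc_auc <- function(labels, scores) {
  if (length(labels) != length(scores)) stopf("labels/scores length mismatch")
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) {
    stopf("AUC is undefined with a single class (have %d positives, %d negatives)",
          n1, n0)
  }
  r <- rank(scores)  # midranks handle ties as 1/2
  auc <- (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  th <- sort(unique(scores), decreasing = TRUE)
  tp <- vapply(th, function(t) sum(scores >= t & labels == 1), numeric(1))
  fp <- vapply(th, function(t) sum(scores >= t & labels == 0), numeric(1))
  curve <- data.frame(threshold = c(Inf, th),
                      fpr = c(0, fp / n0), tpr = c(0, tp / n1))
  list(auc = auc, curve = curve)
}

#' Pool metrics across cross-validation folds
#'
#' Canonical aggregation sums the confusion counts over folds and recomputes
#' every metric from the pooled matrix; AUC is pooled over all fold-wise
#' (label, score) pairs. The per-fold mean of each metric is also reported.
#'
#' @param fold_results list with one element per fold, each a list holding
#'   `labels` and `scores` (glaucoma probabilities) for that fold's test set
#'   (predicted labels are scores > 0.5).
#' @return a list with `pooled` (a `metrics_report` with `auc`) and
#'   `fold_mean` (named numeric vector of per-fold averages).
#' @export
aggregate_cv <- function(fold_results) {
  if (length(fold_results) == 0L) stopf("no fold results to aggregate")
  labels <- unlist(lapply(fold_results, `[[`, "labels"))
  scores <- unlist(lapply(fold_results, `[[`, "scores"))
  pooled <- binary_metrics(confusion(labels, as.integer(scores > 0.5)))
  pooled$auc <- roc_auc(labels, scores)$auc
  per_fold <- lapply(fold_results, function(f) {
    rep <- binary_metrics(confusion(f$labels, as.integer(f$scores > 0.5)))
    c(accuracy = rep$accuracy, sensitivity = rep$sensitivity,
      specificity = rep$specificity, f1 = rep$f1, kappa = rep$kappa,
      auc = roc_auc(f$labels, f$scores)$auc)
  })
  list(pooled = pooled, fold_mean = colMeans(do.call(rbind, per_fold)))
}
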