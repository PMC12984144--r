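# Model evaluation and the multi-dataset cross-validation driver.

#' Evaluate a model on a labelled manifest
#'
#' Loads the images (resized to the model's evaluation size), predicts, and
#' computes the full metrics suite.
#'
#' @param object a `fundus_fit` or `fundus_model`.
#' @param records manifest data frame with `image_path` and `label`.
#' @param image_size evaluation resize; defaults to the fit's training size
#'   (or 224 for a bare model).
#' @param batch_size evaluation batch size.
#' @return a list: `metrics` (a `metrics_report` with `auc`), `cm`,
#'   `roc` (curve data frame), `predictions` (per-sample data frame).
#' @export
evaluate_model <- function(object, records, image_size = NULL, batch_size = 32L) {
  model <- if (inherits(object, "fundus_fit")) object$model else object
  if (is.null(image_size)) {
    image_size <- if (inherits(object, "fundus_fit")) object$config$image_size else 224L
  }
  imgs <- load_split_images(records, image_size)
  labels <- records$label
  ev <- eval_on(model, imgs, labels, batch_size)
  scores <- ev$probs[, 2L]
  predicted <- as.integer(max.col(ev$probs) - 1L)
  cm <- confusion(labels, predicted)
  metrics <- binary_metrics(cm)
  # AUC is undefined on a single-class evaluation set; report it as NA there
  roc <- if (length(unique(labels)) == 2L) roc_auc(labels, scores) else
    list(auc = NA_real_, curve = NULL)
  metrics$auc <- roc$auc
  preds <- data.frame(image_path = records$image_path,
                      label = labels,
                      p_normal = ev$probs[, 1L],
                      p_glaucoma = scores,
                      predicted = predicted)
  list(metrics = metrics, cm = cm, roc = roc$curve, predictions = preds,
       loss = ev$loss)
}

#' Multi-dataset k-fold cross-validation
#'
#' Implements the combined-dataset protocol: per-(dataset, class) balanced
#' folds, and for each iteration the held-out fold as test set with the
#' remaining records split 80/20 into training and validation preserving
#' class balance; a model is trained from scratch in every iteration and the
#' fold results are pooled.
#'
#' @param records manifest data frame.
#' @param k number of folds.
#' @param backbone_cfg a [backbone_config()].
#' @param attention_cfg attention settings for [assemble_model()] (or `NULL`).
#' @param cfg a [train_config()].
#' @param seed master seed; fold assignment, per-fold splits and per-fold
#'   model initializations derive from it.
#' @param verbose print per-epoch progress.
#' @return a list with `fold_metrics` (list of per-fold evaluation results),
#'   `aggregate` (from [aggregate_cv()]) and `folds` (the assignment).
#' @export
run_crossval <- function(records, k = 5L, backbone_cfg, attention_cfg = NULL,
                         cfg, seed = 1L, verbose = FALSE) {
  folds <- make_cv_folds(records, k = k, seed = seed)
  fold_metrics <- vector("list", k)
  fold_results <- vector("list", k)
  for (i in seq_len(k)) {
    plan <- cv_iteration(records, folds, i, seed = derive_seed(seed, i))
    model <- assemble_model(backbone_cfg, attention_cfg,
                            seed = derive_seed(seed, 1000L + i))
    cfg_i <- cfg
    cfg_i$seed <- derive_seed(seed, 2000L + i)
    fit <- train_model(model, plan, cfg_i, verbose = verbose)
    ev <- evaluate_model(fit, plan$test)
    fold_metrics[[i]] <- ev
    fold_results[[i]] <- list(labels = plan$test$label,
                              scores = ev$predictions$p_glaucoma)
  }
  list(fold_metrics = fold_metrics,
       aggregate = aggregate_cv(fold_results),
       folds = folds)
}
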