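# S3 methods for fitted models.

#' @export
print.fundus_fit <- function(x, ...) {
  cat("<fundus_fit>\n")
  print(x$model)
  cat(sprintf("  trained %d epochs on %d images (val %d); best epoch %d, val accuracy %.4f\n",
              nrow(x$history), x$n_train, x$n_val, x$best_epoch, x$best_val_acc))
  invisible(x)
}

#' Summarize a fitted model
#'
#' @param object a `fundus_fit`.
#' @param ... unused.
#' @return the fit, invisibly, after printing the configuration and the
#'   tail of the training history.
#' @export
summary.fundus_fit <- function(object, ...) {
  print(object)
  cfg <- object$config
  cat(sprintf("  recipe: peak lr %.2g, %d warm-up of %d epochs, batch %d, %dpx inputs\n",
              cfg$peak_lr, cfg$warmup_epochs, cfg$epochs, cfg$batch_size,
              cfg$image_size))
  cat("  last epochs:\n")
  print(utils::tail(object$history, 5L), row.names = FALSE)
  invisible(object)
}

#' Predict on new images
#'
#' @param object a `fundus_fit`.
#' @param newdata either a manifest-style data frame with `image_path`, or
#'   an `(S, S, 3)` array / `(S, S, 3, N)` batch in `[0, 1]`.
#' @param type `"prob"` for the full probability data frame, `"class"` for
#'   the predicted labels only.
#' @param ... unused.
#' @return a data frame (`p_normal`, `p_glaucoma`, `predicted`) or a factor.
#' @export
predict.fundus_fit <- function(object, newdata, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  size <- object$config$image_size
  if (is.data.frame(newdata)) {
    imgs <- load_split_images(newdata, size)
    x <- stack_images(imgs)
  } else {
    x <- as_batch(newdata)
    if (dim(x)[1] != size || dim(x)[2] != size) {
      n <- dim(x)[4]
      resized <- lapply(seq_len(n), function(i) resize_image(x[, , , i], size))
      x <- stack_images(resized)
    }
  }
  out <- model_predict(object$model, x)
  if (type == "class") out$predicted else out
}

#' Model coefficients (trainable parameters)
#'
#' @param object a `fundus_fit` or `fundus_model`.
#' @param ... unused.
#' @return the nested list of trainable parameter arrays.
#' @export
coef.fundus_fit <- function(object, ...) model_trainables(object$model)

#' Plot the training history
#'
#' Draws the loss curves (training and validation) and the validation
#' accuracy over epochs.
#'
#' @param x a `fundus_fit`.
#' @param ... passed to [graphics::matplot()].
#' @return the fit, invisibly.
#' @export
plot.fundus_fit <- function(x, ...) {
  h <- x$history
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::matplot(h$epoch, cbind(h$train_loss, h$val_loss), type = "l",
                    lty = 1, col = c("steelblue", "firebrick"),
                    xlab = "epoch", ylab = "cross-entropy loss", ...)
  graphics::legend("topright", c("train", "validation"), lty = 1,
                   col = c("steelblue", "firebrick"), bty = "n")
  graphics::plot(h$epoch, h$val_acc, type = "l", col = "darkgreen",
                 xlab = "epoch", ylab = "validation accuracy")
  graphics::abline(v = x$best_epoch, lty = 3)
  invisible(x)
}

# ---- checkpoints ----------------------------------------------------------

CHECKPOINT_VERSION <- "fundusnet-checkpoint-1"

#' Save a model or fit as a single-file checkpoint
#'
#' @param object a `fundus_fit` or `fundus_model`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(object, path) {
  saveRDS(list(version = CHECKPOINT_VERSION, object = object), path)
  invisible(path)
}

#' Load a checkpoint written by [save_checkpoint()]
#'
#' @param path checkpoint file.
#' @return the stored `fundus_fit` or `fundus_model`.
#' @export
load_checkpoint <- function(path) {
  x <- readRDS(path)
  if (!identical(x$version, CHECKPOINT_VERSION)) {
    stopf("unrecognized checkpoint version in %s", path)
  }
  x$object
}
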