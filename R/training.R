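# Training recipe.
#
# Adam (first-moment decay 0.9), softmax cross-entropy on two logits, a
# learning-rate schedule of linear warm-up from zero over the first
# warm-up fraction followed by cosine decay to zero, and train-time
# augmentation (random area crop, horizontal flip, colour jitter). The
# reference recipe is 100 epochs, 5 warm-up epochs, peak rate 5e-5,
# 224 x 224 inputs; every knob is configurable for desk-scale runs.

#' Training configuration
#'
#' @param epochs total training epochs.
#' @param warmup_epochs epochs of linear warm-up from zero to `peak_lr`.
#' @param peak_lr learning rate reached at the end of warm-up.
#' @param adam_beta1,adam_beta2 Adam moment decays ("momentum" 0.9 is the
#'   first-moment decay; Adam has no classical momentum).
#' @param batch_size minibatch size.
#' @param image_size square input size fed to the network.
#' @param crop_scale range of the random-crop area fraction.
#' @param hflip_prob probability of a horizontal flip.
#' @param jitter maximum relative brightness/contrast/saturation change.
#' @param seed master seed for shuffling and augmentation.
#' @return a `train_config` list.
#' @export
train_config <- function(epochs = 100L, warmup_epochs = 5L, peak_lr = 5e-5,
                         adam_beta1 = 0.9, adam_beta2 = 0.999,
                         batch_size = 32L, image_size = 224L,
                         crop_scale = c(0.8, 1.0), hflip_prob = 0.5,
                         jitter = 0.2, seed = 1L) {
  if (warmup_epochs >= epochs) stopf("warmup_epochs must be smaller than epochs")
  if (peak_lr <= 0) stopf("peak_lr must be positive")
  structure(list(epochs = as.integer(epochs),
                 warmup_epochs = as.integer(warmup_epochs),
                 peak_lr = peak_lr, adam_beta1 = adam_beta1,
                 adam_beta2 = adam_beta2, batch_size = as.integer(batch_size),
                 image_size = as.integer(image_size),
                 crop_scale = crop_scale, hflip_prob = hflip_prob,
                 jitter = jitter, seed = as.integer(seed)),
            class = "train_config")
}

#' Learning rate at a training fraction
#'
#' Linear ramp from 0 to `peak_lr` across the warm-up fraction, then cosine
#' decay from `peak_lr` back to 0 at the end of training.
#'
#' @param frac fraction of training completed, in `[0, 1]`.
#' @param cfg a [train_config()].
#' @return the learning rate.
#' @export
lr_at <- function(frac, cfg) {
  if (any(frac < 0 | frac > 1)) stopf("frac must be within [0, 1]")
  wf <- cfg$warmup_epochs / cfg$epochs
  ramp <- if (wf > 0) frac / wf else rep(1, length(frac))
  ifelse(frac <= wf,
         cfg$peak_lr * ramp,
         cfg$peak_lr * 0.5 * (1 + cos(pi * (frac - wf) / (1 - wf))))
}

#' Train-time augmentation of one image
#'
#' Random square crop (area fraction drawn from `crop_scale`, position
#' uniform), bilinear resize to `image_size`, horizontal flip with
#' probability `hflip_prob`, then brightness/contrast/saturation jitter with
#' factors drawn from `1 +/- jitter`. Uses the current R RNG stream; seed it
#' for reproducibility. With `crop_scale = c(1, 1)`, `hflip_prob = 0` and
#' `jitter = 0` the operation reduces exactly to the evaluation-path resize.
#'
#' @param image `(H, W, 3)` array in `[0, 1]`.
#' @param cfg a [train_config()].
#' @return `(image_size, image_size, 3)` array in `[0, 1]`.
#' @export
augment <- function(image, cfg) {
  d <- dim(image)
  if (length(d) != 3L || d[3] != 3L) stopf("augment expects an (H, W, 3) image")
  side <- min(d[1], d[2])
  area <- runif(1, cfg$crop_scale[1], cfg$crop_scale[2])
  csize <- max(1L, min(side, as.integer(round(side * sqrt(area)))))
  r0 <- if (d[1] > csize) sample.int(d[1] - csize + 1L, 1L) else 1L
  c0 <- if (d[2] > csize) sample.int(d[2] - csize + 1L, 1L) else 1L
  crop <- image[r0:(r0 + csize - 1L), c0:(c0 + csize - 1L), , drop = FALSE]
  out <- resize_image(crop, cfg$image_size)
  if (cfg$hflip_prob > 0 && runif(1) < cfg$hflip_prob) {
    out <- out[, rev(seq_len(dim(out)[2])), , drop = FALSE]
  }
  if (cfg$jitter > 0) {
    f <- runif(3, 1 - cfg$jitter, 1 + cfg$jitter)
    out <- out * f[1]                                   # brightness
    mu <- mean(out)
    out <- (out - mu) * f[2] + mu                       # contrast
    gray <- (out[, , 1] + out[, , 2] + out[, , 3]) / 3  # saturation
    for (ch in 1:3) out[, , ch] <- gray + (out[, , ch] - gray) * f[3]
    out <- clamp01(out)
  }
  out
}

#' Resize an image to a square side (the evaluation-path transform)
#' @param image `(H, W, C)` array.
#' @param size target side in pixels.
#' @return `(size, size, C)` array.
#' @export
resize_image <- function(image, size) {
  d <- dim(image)
  if (d[1] == size && d[2] == size) return(image)
  storage.mode(image) <- "double"
  bilinear_resize(image, as.integer(size), as.integer(size))
}

# ---- Adam -----------------------------------------------------------------

adam_init <- function(n) list(m = numeric(n), v = numeric(n), t = 0L)

adam_step <- function(state, theta, grad, lr, beta1, beta2, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- beta1 * state$m + (1 - beta1) * grad
  state$v <- beta2 * state$v + (1 - beta2) * grad^2
  mhat <- state$m / (1 - beta1^state$t)
  vhat <- state$v / (1 - beta2^state$t)
  list(state = state, theta = theta - lr * mhat / (sqrt(vhat) + eps))
}

# ---- training loop --------------------------------------------------------

load_split_images <- function(records, size) {
  lapply(records$image_path, function(p) {
    img <- read_image(p)
    if (dim(img)[1] != size || dim(img)[2] != size) img <- resize_image(img, size)
    img
  })
}

stack_images <- function(imgs) {
  d <- dim(imgs[[1]])
  x <- array(0, c(d[1], d[2], d[3], length(imgs)))
  for (i in seq_along(imgs)) x[, , , i] <- imgs[[i]]
  x
}

eval_on <- function(model, imgs, labels, batch_size) {
  n <- length(imgs)
  loss <- 0
  correct <- 0L
  probs <- matrix(0, n, 2L)
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    x <- stack_images(imgs[idx])
    out <- model_fw(model, x, train = FALSE, keep = FALSE)
    cl <- ce_loss(out$logits, labels[idx])
    loss <- loss + cl$loss * length(idx)
    correct <- correct + sum(max.col(out$probs) - 1L == labels[idx])
    probs[idx, ] <- out$probs
  }
  list(loss = loss / n, acc = correct / n, probs = probs)
}

#' Train a model on a split plan
#'
#' Runs the full recipe: per-epoch shuffling and augmentation of the training
#' partition, Adam updates at the scheduled learning rate (one rate per
#' epoch, `lr_at(epoch / epochs)`), and per-epoch validation. The returned
#' fit carries the checkpoint with the highest validation accuracy (ties
#' resolved to the earlier epoch) plus the complete history.
#'
#' @param model a [assemble_model()] object.
#' @param split a `split_plan` with nonempty `train` and `val` partitions
#'   (record data frames pointing at image files).
#' @param cfg a [train_config()].
#' @param verbose print one line per epoch.
#' @return an object of class `fundus_fit`.
#' @export
train_model <- function(model, split, cfg, verbose = FALSE) {
  stopifnot(inherits(model, "fundus_model"), inherits(cfg, "train_config"))
  if (nrow(split$train) == 0L || nrow(split$val) == 0L) {
    stopf("train and val partitions must be nonempty")
  }
  train_imgs_raw <- lapply(split$train$image_path, read_image)
  train_labels <- split$train$label
  val_imgs <- load_split_images(split$val, cfg$image_size)
  val_labels <- split$val$label

  tr <- model_trainables(model)
  theta <- flatten_params(tr)
  opt <- adam_init(length(theta))
  n <- length(train_imgs_raw)
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_loss = numeric(), val_acc = numeric(),
                        lr = numeric())
  best <- list(acc = -Inf, epoch = NA_integer_, theta = NULL, buffers = NULL)

  with_seed(cfg$seed, {
    for (epoch in seq_len(cfg$epochs)) {
      lr <- lr_at(epoch / cfg$epochs, cfg)
      ord <- sample.int(n)
      epoch_loss <- 0
      for (start in seq(1L, n, by = cfg$batch_size)) {
        idx <- ord[start:min(start + cfg$batch_size - 1L, n)]
        xb <- stack_images(lapply(train_imgs_raw[idx], augment, cfg = cfg))
        fwd <- model_fw(model, xb, train = TRUE, keep = TRUE)
        model$backbone$buffers <- fwd$buffers
        cl <- ce_loss(fwd$logits, train_labels[idx])
        if (!is.finite(cl$loss)) {
          stopf("non-finite training loss at epoch %d (diverged)", epoch)
        }
        bwd <- model_bw(model, fwd, cl$dlogits)
        g <- flatten_params(bwd$grads)
        st <- adam_step(opt, theta, g, lr, cfg$adam_beta1, cfg$adam_beta2)
        opt <- st$state
        theta <- st$theta
        model <- model_set_trainables(model, unflatten_params(theta, tr))
        epoch_loss <- epoch_loss + cl$loss * length(idx)
      }
      ev <- eval_on(model, val_imgs, val_labels, cfg$batch_size)
      history <- rbind(history,
                       data.frame(epoch = epoch, train_loss = epoch_loss / n,
                                  val_loss = ev$loss, val_acc = ev$acc, lr = lr))
      if (ev$acc > best$acc) {
        best <- list(acc = ev$acc, epoch = epoch, theta = theta,
                     buffers = model$backbone$buffers)
      }
      if (verbose) {
        message(sprintf("epoch %3d  lr %.2e  train %.4f  val %.4f  acc %.4f",
                        epoch, lr, epoch_loss / n, ev$loss, ev$acc))
      }
    }
  })

  best_model <- model_set_trainables(model, unflatten_params(best$theta, tr))
  best_model$backbone$buffers <- best$buffers
  structure(list(model = best_model, final_model = model, history = history,
                 config = cfg, best_epoch = best$epoch,
                 best_val_acc = best$acc,
                 n_train = n, n_val = length(val_imgs)),
            class = "fundus_fit")
}
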