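# Classification head and full-model assembly.
#
# A model is backbone -> (optional hybrid attention) -> global average
# pooling -> fully connected layer with two outputs (normal, glaucoma),
# trained with softmax cross-entropy. Images enter as (S, S, 3) arrays in
# [0, 1]; the forward pass standardizes them to roughly zero mean / unit
# variance ((x - 0.5) / 0.25) before the stem.

INPUT_MEAN <- 0.5
INPUT_SD <- 0.25
CLASS_LEVELS <- c("normal", "glaucoma")

#' Global average pooling
#'
#' Reduces a feature map to one value per channel: the mean over its spatial
#' extent.
#'
#' @param x an `(H, W, C)` feature array.
#' @return numeric vector of length `C`.
#' @export
global_average_pool <- function(x) {
  d <- check_featuremap(x)
  m <- x
  dim(m) <- c(d[1] * d[2], d[3])
  colMeans(m)
}

#' Assemble a classification model
#'
#' Wires a backbone, an optional hybrid attention block and the
#' pooling + fully-connected head into one model. With attention, the head's
#' input width is `2 * C / r` (two recalibrated branches of the reduced map);
#' without, it is the backbone's final channel count `C`.
#'
#' @param backbone_cfg a [backbone_config()].
#' @param attention_cfg `NULL` for the baseline, or a list with elements `r`
#'   (reduction ratio, default 4) and `r2` (MLP bottleneck ratio, default 16).
#' @param seed integer; the full parameter initialization is reproducible
#'   from it.
#' @return an object of class `fundus_model`.
#' @export
assemble_model <- function(backbone_cfg, attention_cfg = NULL, seed = 1L) {
  with_seed(seed, {
    bb <- build_backbone(backbone_cfg)
    C <- bb$final_channels
    att <- NULL
    if (!is.null(attention_cfg)) {
      r <- attention_cfg$r %||% 4L
      r2 <- attention_cfg$r2 %||% 16L
      if (C %% r != 0) {
        stopf("backbone channel count %d is not divisible by attention ratio r = %d", C, r)
      }
      att <- attention_params(C, r = r, r2 = r2)
    }
    head_in <- if (is.null(att)) C else 2L * att$cp
    fc <- init_fc(head_in, 2L)
    structure(list(backbone = bb, attention = att, fc = fc,
                   head_in = head_in, seed = as.integer(seed)),
              class = "fundus_model")
  })
}

# Nested trainable-parameter structure (mirrored exactly by gradients).
model_trainables <- function(model) {
  list(backbone = model$backbone$params,
       attention = if (is.null(model$attention)) NULL
                   else attention_trainables(model$attention),
       fc = model$fc)
}

model_set_trainables <- function(model, tr) {
  model$backbone$params <- tr$backbone
  if (!is.null(model$attention)) {
    model$attention <- attention_set_trainables(model$attention, tr$attention)
  }
  model$fc <- tr$fc
  model
}

#' @export
print.fundus_model <- function(x, ...) {
  cfg <- x$backbone$cfg
  cat(sprintf("<fundus_model> %s-%d (width x%g)\n", cfg$family, cfg$depth,
              cfg$width_multiplier))
  if (is.null(x$attention)) {
    cat("  attention: none (baseline)\n")
  } else {
    cat(sprintf("  attention: hybrid, r = %d, r2 = %d (reduced channels %d)\n",
                x$attention$r, x$attention$r2, x$attention$cp))
  }
  cat(sprintf("  head: GAP + FC(%d -> 2), %s normalization layers\n",
              x$head_in,
              if (cfg$family == "nf_resnet") "no" else
                as.character(count_norm_layers(x$backbone))))
  cat(sprintf("  parameters: %s\n",
              format(length(flatten_params(model_trainables(x))), big.mark = ",")))
  invisible(x)
}

# Full forward pass over a batch of raw images in [0, 1].
# Returns logits, probabilities and (optionally) all caches for backprop.
model_fw <- function(model, images, train = FALSE, keep = FALSE) {
  x4 <- as_batch(images)
  if (dim(x4)[3] != 3L) stopf("images must have 3 channels")
  xn <- (x4 - INPUT_MEAN) / INPUT_SD
  bb_out <- backbone_fw(model$backbone, xn, train = train, keep = keep)
  feats <- bb_out$features
  if (!is.null(model$attention)) {
    att_out <- att_fw(feats, model$attention, keep = keep)
    head_in <- att_out$y
  } else {
    att_out <- NULL
    head_in <- feats
  }
  pool <- gap_fw(head_in)
  logits <- fc_fw(pool, model$fc)
  list(logits = logits, probs = softmax_rows(logits),
       features = feats, attention_out = if (is.null(att_out)) NULL else att_out$y,
       pool = pool, head_in_dims = dim(head_in),
       bb_cache = if (keep) bb_out$cache else NULL,
       att_cache = if (keep) att_out$cache else NULL,
       buffers = bb_out$buffers)
}

# Backprop from a logits gradient down to every trainable parameter.
# Returns gradients mirroring model_trainables(), plus the gradient at the
# attention output (used by Grad-CAM++) and at the backbone features.
model_bw <- function(model, fwd, dlogits) {
  gfc <- fc_bw(fwd$pool, model$fc, dlogits)
  dhead_in <- gap_bw(gfc$dpool, fwd$head_in_dims)
  if (!is.null(model$attention)) {
    datt <- dhead_in
    abw <- att_bw(datt, fwd$att_cache, model$attention)
    dfeats <- abw$dx
    att_grads <- abw$grads
  } else {
    datt <- NULL
    dfeats <- dhead_in
    att_grads <- NULL
  }
  bb <- model$backbone
  bbw <- if (bb$cfg$family == "nf_resnet") {
    nf_backbone_bw(bb$spec, bb$params, bb$final_beta, fwd$bb_cache, dfeats)
  } else {
    bn_backbone_bw(bb$spec, bb$params, fwd$bb_cache, dfeats)
  }
  list(grads = list(backbone = bbw$grads, attention = att_grads, fc = gfc$grads),
       d_attention_out = datt, d_features = dfeats)
}

#' Predict class scores for a batch of images
#'
#' @param model a `fundus_model`.
#' @param images `(S, S, 3)` image or `(S, S, 3, N)` batch in `[0, 1]`.
#' @return a data frame with columns `p_normal`, `p_glaucoma` and
#'   `predicted` (factor with levels normal/glaucoma).
#' @export
model_predict <- function(model, images) {
  out <- model_fw(model, images, train = FALSE, keep = FALSE)
  data.frame(p_normal = out$probs[, 1L], p_glaucoma = out$probs[, 2L],
             predicted = factor(CLASS_LEVELS[max.col(out$probs)],
                                levels = CLASS_LEVELS))
}
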