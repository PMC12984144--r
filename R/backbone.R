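# Feature-extractor backbones.
#
# Two families share the classic bottleneck ResNet topology (7x7/stride-2
# stem, 3x3/stride-2 max pool, four stages of bottleneck blocks, total
# stride 32, final width 2048 * width_multiplier):
#
#  * nf_resnet -- no normalization layers anywhere. Convolutions use scaled
#    weight standardization with a per-channel learnable gain, activations
#    are gamma-scaled ReLUs (gamma = 1/sd(relu(Z)), Z standard normal), and
#    residual branches are variance-preserving: block l computes
#    x + alpha * f(x / beta_l) with alpha = 0.2 and beta_l tracking the
#    analytically expected signal standard deviation (reset at downsampling
#    transitions, growing by alpha^2 per block in between).
#  * resnet -- the standard batch-normalized post-activation bottleneck,
#    used as the baseline / negative control.
#
# `width_multiplier` scales every width so the same code runs at desk scale
# (e.g. 0.125 gives a 256-channel final stage).

STAGE_LAYOUTS <- list(`26` = c(2L, 2L, 2L, 2L),
                      `50` = c(3L, 4L, 6L, 3L),
                      `101` = c(3L, 4L, 23L, 3L))

#' Backbone configuration
#'
#' @param family `"nf_resnet"` (normalization-free) or `"resnet"`
#'   (batch-normalized baseline).
#' @param depth 26, 50 or 101 layers (bottleneck layouts
#'   `[2,2,2,2]`, `[3,4,6,3]`, `[3,4,23,3]`).
#' @param width_multiplier positive scale on all channel widths; 1 gives the
#'   full-size network (2048 final channels), 0.125 a desk-scale one.
#' @param input_size expected square input size in pixels.
#' @return a `backbone_config` list.
#' @export
backbone_config <- function(family = c("nf_resnet", "resnet"),
                            depth = 50, width_multiplier = 1,
                            input_size = 224) {
  family <- match.arg(family)
  key <- as.character(depth)
  if (!key %in% names(STAGE_LAYOUTS)) {
    stopf("unsupported depth %s (supported: 26, 50, 101)", key)
  }
  if (width_multiplier <= 0) stopf("width_multiplier must be positive")
  structure(list(family = family, depth = as.integer(depth),
                 width_multiplier = width_multiplier,
                 blocks_per_stage = STAGE_LAYOUTS[[key]],
                 stem_channels = max(1L, as.integer(round(64 * width_multiplier))),
                 stage_channels = pmax(1L, as.integer(round(c(256, 512, 1024, 2048) *
                                                              width_multiplier))),
                 input_size = as.integer(input_size)),
            class = "backbone_config")
}

#' Build a backbone feature extractor
#'
#' Instantiates the configured backbone with freshly initialized parameters.
#' Weight-standardized convolutions are drawn fan-in-scaled Gaussian with
#' unit gains and zero biases; batch-norm scales start at 1.
#'
#' @param cfg a [backbone_config()].
#' @param seed optional integer; when given, initialization is reproducible.
#' @return an object of class `fundus_backbone`.
#' @export
build_backbone <- function(cfg, seed = NULL) {
  stopifnot(inherits(cfg, "backbone_config"))
  build <- function() {
    nf <- cfg$family == "nf_resnet"
    spec <- list()
    params <- list()
    buffers <- list()
    params$stem <- if (nf) init_conv(7L, 7L, 3L, cfg$stem_channels)
                   else init_conv(7L, 7L, 3L, cfg$stem_channels, ws = FALSE)
    if (!nf) {
      params$stem_bn <- list(gamma = rep(1, cfg$stem_channels),
                             beta = rep(0, cfg$stem_channels))
      buffers$stem_bn <- list(rmean = rep(0, cfg$stem_channels),
                              rvar = rep(1, cfg$stem_channels))
    }
    in_ch <- cfg$stem_channels
    expected_var <- 1.0
    params$stages <- vector("list", 4L)
    buffers$stages <- vector("list", 4L)
    for (s in 1:4) {
      nb <- cfg$blocks_per_stage[s]
      out_ch <- cfg$stage_channels[s]
      mid_ch <- max(1L, out_ch %/% 4L)
      params$stages[[s]] <- vector("list", nb)
      buffers$stages[[s]] <- vector("list", nb)
      spec[[s]] <- vector("list", nb)
      for (b in seq_len(nb)) {
        stride <- if (s > 1L && b == 1L) 2L else 1L
        transition <- b == 1L  # first block of every stage rewires channels
        beta <- sqrt(expected_var)
        spec[[s]][[b]] <- list(in_ch = in_ch, mid_ch = mid_ch, out_ch = out_ch,
                               stride = stride, transition = transition,
                               beta = beta)
        if (nf) {
          blk <- list(c1 = init_conv(1L, 1L, in_ch, mid_ch),
                      c2 = init_conv(3L, 3L, mid_ch, mid_ch),
                      c3 = init_conv(1L, 1L, mid_ch, out_ch),
                      sc = if (transition) init_conv(1L, 1L, in_ch, out_ch) else NULL)
        } else {
          blk <- list(c1 = init_conv(1L, 1L, in_ch, mid_ch, ws = FALSE),
                      bn1 = list(gamma = rep(1, mid_ch), beta = rep(0, mid_ch)),
                      c2 = init_conv(3L, 3L, mid_ch, mid_ch, ws = FALSE),
                      bn2 = list(gamma = rep(1, mid_ch), beta = rep(0, mid_ch)),
                      c3 = init_conv(1L, 1L, mid_ch, out_ch, ws = FALSE),
                      bn3 = list(gamma = rep(1, out_ch), beta = rep(0, out_ch)),
                      sc = if (transition) init_conv(1L, 1L, in_ch, out_ch, ws = FALSE) else NULL,
                      bnsc = if (transition) list(gamma = rep(1, out_ch),
                                                  beta = rep(0, out_ch)) else NULL)
          buffers$stages[[s]][[b]] <- list(
            bn1 = list(rmean = rep(0, mid_ch), rvar = rep(1, mid_ch)),
            bn2 = list(rmean = rep(0, mid_ch), rvar = rep(1, mid_ch)),
            bn3 = list(rmean = rep(0, out_ch), rvar = rep(1, out_ch)),
            bnsc = if (transition) list(rmean = rep(0, out_ch),
                                        rvar = rep(1, out_ch)) else NULL)
        }
        params$stages[[s]][[b]] <- blk
        expected_var <- if (transition) 1 + NF_ALPHA^2 else expected_var + NF_ALPHA^2
        in_ch <- out_ch
      }
    }
    structure(list(cfg = cfg, spec = spec, params = params, buffers = buffers,
                   final_channels = in_ch,
                   final_beta = sqrt(expected_var)),
              class = "fundus_backbone")
  }
  if (is.null(seed)) build() else with_seed(seed, build())
}

# ---- normalization-free forward/backward ----------------------------------

nf_block_fw <- function(x, blk, p) {
  xb <- x / blk$beta
  z <- act_fw(xb)
  f1 <- conv_ws_fw(z, p$c1)
  r1 <- act_fw(f1$y)
  f2 <- conv_ws_fw(r1, p$c2, stride = blk$stride, pad = 1L)
  r2 <- act_fw(f2$y)
  f3 <- conv_ws_fw(r2, p$c3)
  if (blk$transition) {
    fs <- conv_ws_fw(z, p$sc, stride = blk$stride)
    y <- fs$y + NF_ALPHA * f3$y
  } else {
    fs <- NULL
    y <- x + NF_ALPHA * f3$y
  }
  list(y = y, cache = list(xb = xb, f1 = f1, a1 = f1$y, f2 = f2, a2 = f2$y,
                           f3 = f3, fs = fs))
}

nf_block_bw <- function(dy, cache, blk, p) {
  g3 <- conv_ws_bw(cache$f3, p$c3, NF_ALPHA * dy)
  da2 <- act_bw(cache$a2, g3$dx)
  g2 <- conv_ws_bw(cache$f2, p$c2, da2)
  da1 <- act_bw(cache$a1, g2$dx)
  g1 <- conv_ws_bw(cache$f1, p$c1, da1)
  dz <- g1$dx
  grads <- list(c1 = g1$grads, c2 = g2$grads, c3 = g3$grads, sc = NULL)
  if (blk$transition) {
    gs <- conv_ws_bw(cache$fs, p$sc, dy)
    grads$sc <- gs$grads
    dz <- dz + gs$dx
    dx <- act_bw(cache$xb, dz) / blk$beta
  } else {
    dx <- dy + act_bw(cache$xb, dz) / blk$beta
  }
  list(dx = dx, grads = grads)
}

nf_backbone_fw <- function(bb_spec, params, final_beta, x4, keep = TRUE) {
  stem <- conv_ws_fw(x4, params$stem, stride = 2L, pad = 3L)
  mp <- maxpool_fw(stem$y, 3L, 2L, 1L)
  h <- mp$y
  caches <- list(stem = if (keep) stem else NULL,
                 mp_idx = if (keep) mp$idx else NULL,
                 mp_in_dims = dim(stem$y),
                 blocks = if (keep) vector("list", 4L) else NULL)
  for (s in 1:4) {
    if (keep) caches$blocks[[s]] <- vector("list", length(bb_spec[[s]]))
    for (b in seq_along(bb_spec[[s]])) {
      out <- nf_block_fw(h, bb_spec[[s]][[b]], params$stages[[s]][[b]])
      if (keep) caches$blocks[[s]][[b]] <- c(out$cache, list(x_in = h))
      h <- out$y
    }
  }
  pre <- h / final_beta
  feats <- act_fw(pre)
  caches$pre_act_in <- if (keep) h else NULL
  list(features = feats, cache = caches)
}

nf_backbone_bw <- function(bb_spec, params, final_beta, cache, dfeats) {
  dh <- act_bw(cache$pre_act_in / final_beta, dfeats) / final_beta
  grads <- list(stem = NULL, stages = vector("list", 4L))
  for (s in 4:1) {
    nb <- length(bb_spec[[s]])
    grads$stages[[s]] <- vector("list", nb)
    for (b in nb:1) {
      bc <- cache$blocks[[s]][[b]]
      out <- nf_block_bw(dh, bc, bb_spec[[s]][[b]], params$stages[[s]][[b]])
      grads$stages[[s]][[b]] <- out$grads
      dh <- out$dx
    }
  }
  dstem_out <- maxpool_bw(dh, cache$mp_idx,
                          cache$mp_in_dims[1], cache$mp_in_dims[2])
  gs <- conv_ws_bw(cache$stem, params$stem, dstem_out)
  grads$stem <- gs$grads
  list(grads = grads, dx = gs$dx)
}

# ---- batch-normalized baseline forward/backward ----------------------------

bn_block_fw <- function(x, blk, p, buf, train) {
  f1 <- conv_fw(x, p$c1$w, rep(0, dim(p$c1$w)[4]))
  b1 <- bn_fw(f1, p$bn1, buf$bn1, train)
  r1 <- relu_fw(b1$y)
  f2 <- conv_fw(r1, p$c2$w, rep(0, dim(p$c2$w)[4]), stride = blk$stride, pad = 1L)
  b2 <- bn_fw(f2, p$bn2, buf$bn2, train)
  r2 <- relu_fw(b2$y)
  f3 <- conv_fw(r2, p$c3$w, rep(0, dim(p$c3$w)[4]))
  b3 <- bn_fw(f3, p$bn3, buf$bn3, train)
  if (blk$transition) {
    fs <- conv_fw(x, p$sc$w, rep(0, dim(p$sc$w)[4]), stride = blk$stride)
    bs <- bn_fw(fs, p$bnsc, buf$bnsc, train)
    pre <- bs$y + b3$y
  } else {
    bs <- NULL
    pre <- x + b3$y
  }
  y <- relu_fw(pre)
  newbuf <- list(bn1 = b1$buf, bn2 = b2$buf, bn3 = b3$buf,
                 bnsc = if (blk$transition) bs$buf else NULL)
  list(y = y, buf = newbuf,
       cache = list(x = as_batch(x), r1 = r1, r2 = r2, b1 = b1, b2 = b2, b3 = b3,
                    bs = bs, f1x = as_batch(x), pre = pre))
}

bn_block_bw <- function(dy, cache, blk, p) {
  dpre <- relu_bw(cache$pre, dy)
  gb3 <- bn_bw(cache$b3, p$bn3, dpre)
  g3 <- conv_bw(cache$r2, p$c3$w, gb3$dx)
  dr2 <- relu_bw(cache$b2$y, g3$dx)
  gb2 <- bn_bw(cache$b2, p$bn2, dr2)
  g2 <- conv_bw(cache$r1, p$c2$w, gb2$dx, stride = blk$stride, pad = 1L)
  dr1 <- relu_bw(cache$b1$y, g2$dx)
  gb1 <- bn_bw(cache$b1, p$bn1, dr1)
  g1 <- conv_bw(cache$x, p$c1$w, gb1$dx)
  grads <- list(c1 = list(w = g1$dw), bn1 = gb1$grads,
                c2 = list(w = g2$dw), bn2 = gb2$grads,
                c3 = list(w = g3$dw), bn3 = gb3$grads,
                sc = NULL, bnsc = NULL)
  dx <- g1$dx
  if (blk$transition) {
    gbs <- bn_bw(cache$bs, p$bnsc, dpre)
    gsc <- conv_bw(cache$x, p$sc$w, gbs$dx, stride = blk$stride)
    grads$sc <- list(w = gsc$dw)
    grads$bnsc <- gbs$grads
    dx <- dx + gsc$dx
  } else {
    dx <- dx + dpre
  }
  list(dx = dx, grads = grads)
}

bn_backbone_fw <- function(bb_spec, params, buffers, x4, train, keep = TRUE) {
  x4 <- as_batch(x4)
  f0 <- conv_fw(x4, params$stem$w, rep(0, dim(params$stem$w)[4]),
                stride = 2L, pad = 3L)
  b0 <- bn_fw(f0, params$stem_bn, buffers$stem_bn, train)
  r0 <- relu_fw(b0$y)
  mp <- maxpool_fw(r0, 3L, 2L, 1L)
  h <- mp$y
  caches <- list(x4 = x4, b0 = b0, mp_idx = mp$idx, mp_in_dims = dim(r0),
                 blocks = vector("list", 4L))
  buffers$stem_bn <- b0$buf
  for (s in 1:4) {
    caches$blocks[[s]] <- vector("list", length(bb_spec[[s]]))
    for (b in seq_along(bb_spec[[s]])) {
      out <- bn_block_fw(h, bb_spec[[s]][[b]], params$stages[[s]][[b]],
                         buffers$stages[[s]][[b]], train)
      buffers$stages[[s]][[b]] <- out$buf
      if (keep) caches$blocks[[s]][[b]] <- out$cache
      h <- out$y
    }
  }
  list(features = h, cache = if (keep) caches else NULL, buffers = buffers)
}

bn_backbone_bw <- function(bb_spec, params, cache, dfeats) {
  dh <- dfeats
  grads <- list(stem = NULL, stem_bn = NULL, stages = vector("list", 4L))
  for (s in 4:1) {
    nb <- length(bb_spec[[s]])
    grads$stages[[s]] <- vector("list", nb)
    for (b in nb:1) {
      out <- bn_block_bw(dh, cache$blocks[[s]][[b]], bb_spec[[s]][[b]],
                         params$stages[[s]][[b]])
      grads$stages[[s]][[b]] <- out$grads
      dh <- out$dx
    }
  }
  dr0 <- maxpool_bw(dh, cache$mp_idx, cache$mp_in_dims[1], cache$mp_in_dims[2])
  dr0 <- relu_bw(cache$b0$y, dr0)
  gb0 <- bn_bw(cache$b0, params$stem_bn, dr0)
  g0 <- conv_bw(cache$x4, params$stem$w, gb0$dx, stride = 2L, pad = 3L)
  grads$stem <- list(w = g0$dw)
  grads$stem_bn <- gb0$grads
  list(grads = grads, dx = g0$dx)
}

backbone_fw <- function(bb, x4, train = FALSE, keep = TRUE) {
  if (bb$cfg$family == "nf_resnet") {
    out <- nf_backbone_fw(bb$spec, bb$params, bb$final_beta, as_batch(x4), keep)
    out$buffers <- bb$buffers
    out
  } else {
    bn_backbone_fw(bb$spec, bb$params, bb$buffers, x4, train, keep)
  }
}

#' Extract backbone features
#'
#' Runs a batch of images through the backbone in evaluation mode and returns
#' the last convolutional stage's activations (the map the attention block
#' consumes).
#'
#' @param bb a [build_backbone()] object.
#' @param images an `(S, S, 3)` image or `(S, S, 3, N)` batch, values in
#'   any finite range (standardize beforehand if desired).
#' @return an `(H, W, C, N)` feature array with `H = W = floor(S / 32)` and
#'   `C = 2048 * width_multiplier`.
#' @export
extract_features <- function(bb, images) {
  stopifnot(inherits(bb, "fundus_backbone"))
  x4 <- as_batch(images)
  if (dim(x4)[3] != 3L) stopf("images must have 3 channels, got %d", dim(x4)[3])
  if (!all(is.finite(x4))) stopf("images contain non-finite values")
  backbone_fw(bb, x4, train = FALSE, keep = FALSE)$features
}

# Count normalization layers (structural census used by tests and summaries).
count_norm_layers <- function(bb) {
  n <- if (!is.null(bb$params$stem_bn)) 1L else 0L
  for (s in 1:4) for (b in seq_along(bb$params$stages[[s]])) {
    blk <- bb$params$stages[[s]][[b]]
    n <- n + sum(c("bn1", "bn2", "bn3", "bnsc") %in% names(blk) &
                   !vapply(blk[c("bn1", "bn2", "bn3", "bnsc")], is.null, logical(1)))
  }
  n
}
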