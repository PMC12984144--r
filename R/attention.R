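# Hybrid channel + spatial attention.
#
# The block sits between the feature extractor and the classification head:
#   1. a pointwise convolution compresses C channels to C' = C / r;
#   2. a channel-attention branch pools the reduced map over space (mean and
#      max), pushes both descriptors through a shared two-layer MLP, sums and
#      squashes them into a per-channel gate in (0, 1);
#   3. a spatial-attention branch pools across channels (mean and max),
#      convolves the two stacked maps with a 7x7 kernel (padding 3) and
#      squashes into a per-pixel gate in (0, 1);
#   4. the reduced map is recalibrated by each gate and the two branches are
#      concatenated along channels (channel branch first), giving 2C'
#      channels.

#' Create hybrid attention parameters
#'
#' Initializes the learnable weights of the hybrid attention block for a
#' feature map with `channels` input channels: the pointwise reduction
#' convolution (with bias), the shared channel-MLP (`w0`, `w1`, no biases)
#' and the 7x7 spatial kernel (with bias). Weights are drawn fan-in-scaled
#' Gaussian; biases start at zero. Seed the R RNG beforehand for
#' reproducibility.
#'
#' @param channels number of incoming channels `C` (must be divisible by `r`).
#' @param r channel reduction ratio of the pointwise convolution.
#' @param r2 bottleneck ratio of the channel-attention MLP; the hidden width
#'   is `max(1, floor(C' / r2))`.
#' @return an object of class `attention_params`.
#' @export
attention_params <- function(channels, r = 4, r2 = 16) {
  if (channels %% r != 0) {
    stopf("channel count %d is not divisible by reduction ratio r = %d", channels, r)
  }
  cp <- channels %/% r
  hidden <- max(1L, cp %/% r2)
  ap <- list(
    channels = as.integer(channels),
    r = as.integer(r),
    r2 = as.integer(r2),
    cp = as.integer(cp),
    hidden = as.integer(hidden),
    reduce = init_conv(1L, 1L, channels, cp, ws = FALSE),
    w0 = matrix(rnorm(hidden * cp, sd = 1 / sqrt(cp)), hidden, cp),
    w1 = matrix(rnorm(cp * hidden, sd = 1 / sqrt(hidden)), cp, hidden),
    spatial = list(w = array(rnorm(7 * 7 * 2, sd = 1 / sqrt(7 * 7 * 2)), c(7L, 7L, 2L, 1L)),
                   b = 0)
  )
  ap$reduce$b <- rep(0, cp)
  class(ap) <- "attention_params"
  ap
}

# extract the trainable leaves (kept separate from the structural fields)
attention_trainables <- function(ap) {
  list(reduce = ap$reduce, w0 = ap$w0, w1 = ap$w1, spatial = ap$spatial)
}

attention_set_trainables <- function(ap, tr) {
  ap$reduce <- tr$reduce
  ap$w0 <- tr$w0
  ap$w1 <- tr$w1
  ap$spatial <- tr$spatial
  ap
}

check_featuremap <- function(x) {
  d <- dim(x)
  if (is.null(d) || length(d) != 3L) stopf("feature map must be an (H, W, C) array")
  if (any(d < 1L)) stopf("feature map dimensions must be at least 1")
  if (!all(is.finite(x))) stopf("feature map contains non-finite values")
  invisible(d)
}

#' Pointwise channel reduction
#'
#' Applies the attention block's 1x1 convolution (with bias, no nonlinearity)
#' reducing `C` channels to `C / r`.
#'
#' @param x feature map, an `(H, W, C)` array.
#' @param params an [attention_params()] object built for `C` channels.
#' @return an `(H, W, C/r)` array.
#' @export
reduce_channels <- function(x, params) {
  d <- check_featuremap(x)
  if (d[3] != params$channels) {
    stopf("feature map has %d channels but params expect %d", d[3], params$channels)
  }
  if (d[3] %% params$r != 0) {
    stopf("channel count %d is not divisible by reduction ratio r = %d", d[3], params$r)
  }
  y <- conv_fw(x, params$reduce$w, params$reduce$b)
  array(y, dim(y)[1:3])
}

#' Spatial mean and max channel descriptors
#'
#' Pools a reduced feature map over its spatial extent, returning the
#' per-channel mean and per-channel maximum used by the channel-attention MLP.
#'
#' @param xr reduced feature map, an `(H, W, C')` array.
#' @return a list with numeric vectors `avg` and `max`, each of length `C'`.
#' @export
channel_descriptors <- function(xr) {
  d <- check_featuremap(xr)
  m <- xr
  dim(m) <- c(d[1] * d[2], d[3])
  list(avg = colMeans(m), max = apply(m, 2L, max))
}

#' Channel attention map
#'
#' Feeds the two pooled descriptors through the shared bottleneck MLP
#' (`sigmoid(W1 relu(W0 avg) + W1 relu(W0 max))`), producing one gate per
#' reduced channel, each strictly inside (0, 1).
#'
#' @param avg,max per-channel descriptors of length `C'`.
#' @param params an [attention_params()] object.
#' @return numeric vector of length `C'` (conceptually a `(C', 1, 1)` map).
#' @export
channel_attention <- function(avg, max, params) {
  cp <- ncol(params$w0)
  if (length(avg) != cp || length(max) != cp) {
    stopf("descriptor length must be %d to match the MLP weights", cp)
  }
  za <- params$w1 %*% relu_fw(params$w0 %*% avg)
  zm <- params$w1 %*% relu_fw(params$w0 %*% max)
  as.numeric(sigmoid(za + zm))
}

#' Spatial attention map
#'
#' Pools the reduced map across channels (mean and max), convolves the
#' two stacked 2-d maps with the 7x7 kernel (padding 3, so the spatial size
#' is preserved) and applies a sigmoid.
#'
#' @param xr reduced feature map, an `(H, W, C')` array.
#' @param params an [attention_params()] object.
#' @return an `(H, W)` matrix with entries strictly inside (0, 1).
#' @export
spatial_attention <- function(xr, params) {
  d <- check_featuremap(xr)
  s <- array(0, c(d[1], d[2], 2L))
  xp <- aperm(xr, c(3L, 1L, 2L))
  dim(xp) <- c(d[3], d[1] * d[2])
  s[, , 1L] <- colMeans(xp)
  s[, , 2L] <- apply(xp, 2L, base::max)
  a <- conv_fw(s, params$spatial$w, params$spatial$b, stride = 1L, pad = 3L)
  matrix(sigmoid(a), d[1], d[2])
}

#' Hybrid attention forward pass
#'
#' Full block: channel reduction, channel- and spatial-attention gating of
#' the reduced map, and concatenation of the two recalibrated branches along
#' the channel axis (channel branch first).
#'
#' @param x feature map, an `(H, W, C)` array with `C` divisible by the
#'   block's reduction ratio.
#' @param params an [attention_params()] object.
#' @return an `(H, W, 2 * C / r)` array.
#' @export
hybrid_forward <- function(x, params) {
  out <- att_fw(as_batch(x), params, keep = FALSE)
  array(out$y, dim(out$y)[1:3])
}

# ---- batched forward/backward used by the assembled model ------------------

att_fw <- function(x4, ap, keep = TRUE) {
  d <- dim(x4)
  if (d[3] != ap$channels) {
    stopf("feature map has %d channels but attention params expect %d", d[3], ap$channels)
  }
  H <- d[1]; W <- d[2]; N <- d[4]
  cp <- ap$cp
  xr <- conv_fw(x4, ap$reduce$w, ap$reduce$b)

  # channel descriptors over space
  xm <- xr
  dim(xm) <- c(H * W, cp * N)
  avg <- matrix(colMeans(xm), cp, N)
  idx_sp <- max.col(t(xm), ties.method = "first")      # argmax over H*W
  mx <- matrix(xm[cbind(idx_sp, seq_along(idx_sp))], cp, N)

  # shared MLP on both descriptors
  ha <- relu_fw(ap$w0 %*% avg)
  hm <- relu_fw(ap$w0 %*% mx)
  zc <- ap$w1 %*% ha + ap$w1 %*% hm
  mc <- sigmoid(zc)                                     # (cp, N)

  # channel-pooled 2-d maps
  xp <- aperm(xr, c(3L, 1L, 2L, 4L))
  dim(xp) <- c(cp, H * W * N)
  smean <- colMeans(xp)
  idx_ch <- max.col(t(xp), ties.method = "first")       # argmax over channels
  smax <- xp[cbind(idx_ch, seq_along(idx_ch))]
  stack <- array(0, c(H, W, 2L, N))
  stack[, , 1L, ] <- smean
  stack[, , 2L, ] <- smax
  as_ <- conv_fw(stack, ap$spatial$w, ap$spatial$b, stride = 1L, pad = 3L)
  ms <- sigmoid(as_)                                    # (H, W, 1, N)

  mcb <- array(rep(mc, each = H * W), c(H, W, cp, N))
  msb <- ms[, , rep(1L, cp), , drop = FALSE]
  ych <- xr * mcb
  ysp <- xr * msb
  y <- array(0, c(H, W, 2L * cp, N))
  y[, , seq_len(cp), ] <- ych
  y[, , cp + seq_len(cp), ] <- ysp

  cache <- if (keep) {
    list(x4 = x4, xr = xr, avg = avg, mx = mx, idx_sp = idx_sp,
         ha = ha, hm = hm, mc = mc, idx_ch = idx_ch, stack = stack,
         ms = ms, mcb = mcb, msb = msb, dims = c(H, W, cp, N))
  } else NULL
  list(y = y, cache = cache)
}

att_bw <- function(dy, cache, ap) {
  H <- cache$dims[1]; W <- cache$dims[2]; cp <- cache$dims[3]; N <- cache$dims[4]
  xr <- cache$xr
  dych <- dy[, , seq_len(cp), , drop = FALSE]
  dysp <- dy[, , cp + seq_len(cp), , drop = FALSE]

  # --- channel branch ---
  dxr <- dych * cache$mcb
  tmp <- dych * xr
  dim(tmp) <- c(H * W, cp * N)
  dmc <- matrix(colSums(tmp), cp, N)
  dzc <- dmc * cache$mc * (1 - cache$mc)
  dw1 <- dzc %*% t(cache$ha + cache$hm)
  dha <- (t(ap$w1) %*% dzc) * (cache$ha > 0)
  dhm <- (t(ap$w1) %*% dzc) * (cache$hm > 0)
  dw0 <- dha %*% t(cache$avg) + dhm %*% t(cache$mx)
  davg <- t(ap$w0) %*% dha
  dmx <- t(ap$w0) %*% dhm
  # spread the avg gradient uniformly over space; route the max gradient to
  # the argmax pixel of each channel
  dxr_flat <- matrix(rep(as.numeric(davg) / (H * W), each = H * W), H * W, cp * N)
  pos <- cbind(cache$idx_sp, seq_len(cp * N))
  dxr_flat[pos] <- dxr_flat[pos] + as.numeric(dmx)
  dxr <- dxr + array(dxr_flat, c(H, W, cp, N))

  # --- spatial branch ---
  dxr <- dxr + dysp * cache$msb
  dms <- dysp * xr
  dms <- array(rowSums(matrix(aperm(dms, c(1L, 2L, 4L, 3L)), ncol = cp)),
               c(H, W, 1L, N))
  das <- dms * cache$ms * (1 - cache$ms)
  gsp <- conv_bw(cache$stack, ap$spatial$w, das, stride = 1L, pad = 3L)
  dstack <- gsp$dx
  dmean_map <- dstack[, , 1L, , drop = FALSE]  # (H, W, 1, N)
  dmax_map <- dstack[, , 2L, , drop = FALSE]
  # mean over channels: spread /cp; max over channels: scatter to argmax channel
  dxp <- matrix(rep(as.numeric(dmean_map) / cp, each = cp), cp, H * W * N)
  posc <- cbind(cache$idx_ch, seq_len(H * W * N))
  dxp[posc] <- dxp[posc] + as.numeric(dmax_map)
  dxp <- array(dxp, c(cp, H, W, N))
  dxr <- dxr + aperm(dxp, c(2L, 3L, 1L, 4L))

  # --- reduction conv ---
  gred <- conv_bw(cache$x4, ap$reduce$w, dxr, stride = 1L, pad = 0L)
  list(dx = gred$dx,
       grads = list(reduce = list(w = gred$dw, b = gred$db),
                    w0 = dw0, w1 = dw1,
                    spatial = list(w = gsp$dw, b = gsp$db)))
}
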