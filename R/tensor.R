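# Low-level differentiable layers over the C++ compute core.
#
# Activations are (H, W, C, N) double arrays; conv kernels are
# (KH, KW, Cin, Cout). Every *_fw returns the output plus whatever the
# matching *_bw needs.

# Variance-preserving gain for a ReLU applied to a unit-variance,
# zero-mean input: 1 / sd(relu(Z)), Z ~ N(0, 1).
GAMMA_RELU <- sqrt(2 / (1 - 1 / pi))

# Default residual-branch scale of the normalization-free blocks.
NF_ALPHA <- 0.2

as_batch <- function(x) {
  d <- dim(x)
  if (length(d) == 3L) {
    dim(x) <- c(d, 1L)
  } else if (length(d) != 4L) {
    stopf("expected a 3-d (H, W, C) or 4-d (H, W, C, N) array")
  }
  storage.mode(x) <- "double"
  x
}

conv_fw <- function(x, w, b, stride = 1L, pad = 0L) {
  conv2d_fw(as_batch(x), w, b, as.integer(stride), as.integer(pad))
}

conv_bw <- function(x, w, dy, stride = 1L, pad = 0L) {
  conv2d_bw(as_batch(x), w, as_batch(dy), as.integer(stride), as.integer(pad))
}

# ---- scaled weight standardization --------------------------------------

#' Scaled weight standardization of a convolution kernel
#'
#' Re-parameterizes a convolution kernel so that, per output channel, the
#' weights have zero mean and are rescaled by
#' `gain / sqrt(fan_in * var + eps)`, where `fan_in = kh * kw * in_channels`
#' and `var` is the population variance of that channel's weights. This is
#' the standardization used throughout the normalization-free backbones in
#' place of batch normalization; the input kernel is not modified.
#'
#' @param weights either a 4-d kernel array `(kh, kw, in_channels,
#'   out_channels)` or a matrix with one output channel per row.
#' @param gain per-output-channel positive scale (recycled if length 1).
#' @param eps small positive guard added to `fan_in * var` so constant
#'   kernels standardize to zero rather than dividing by zero.
#' @return standardized kernel with the same shape as `weights`.
#' @examples
#' standardize_weights(matrix(c(1, -1), 1, 2))  # -> (0.7071, -0.7071)
#' @export
standardize_weights <- function(weights, gain = 1, eps = 1e-4) {
  if (is.matrix(weights)) {
    wm <- t(weights)  # (fan, Cout)
    out_dim <- NULL
  } else {
    d <- dim(weights)
    if (length(d) != 4L) stopf("weights must be a matrix or a 4-d array")
    wm <- matrix(weights, prod(d[1:3]), d[4])
    out_dim <- d
  }
  if (nrow(wm) < 1L) stopf("fan-in must be at least 1")
  gain <- rep_len(gain, ncol(wm))
  mu <- colMeans(wm)
  a <- sweep(wm, 2L, mu)
  s <- sqrt(colSums(a * a) + eps)  # colSums(a^2) = fan_in * population var
  ws <- sweep(a, 2L, gain / s, `*`)
  if (is.null(out_dim)) t(ws) else array(ws, out_dim)
}

# Gradient of the standardization: given dL/d(ws) returns dL/dw and dL/dgain.
standardize_weights_bw <- function(weights, gain, dws, eps = 1e-4) {
  d <- dim(weights)
  fan <- prod(d[1:3])
  wm <- matrix(weights, fan, d[4])
  gm <- matrix(dws, fan, d[4])
  gain <- rep_len(gain, d[4])
  mu <- colMeans(wm)
  a <- sweep(wm, 2L, mu)
  s <- sqrt(colSums(a * a) + eps)
  ga <- colSums(gm * a)
  dgain <- ga / s
  da <- sweep(gm, 2L, gain / s, `*`) - sweep(a, 2L, gain * ga / s^3, `*`)
  dw <- sweep(da, 2L, colMeans(da))
  list(dw = array(dw, d), dgain = dgain)
}

# Standardized convolution (the NF building block): returns the cache the
# backward pass needs (input and the standardized kernel).
conv_ws_fw <- function(x, p, stride = 1L, pad = 0L) {
  wsw <- standardize_weights(p$w, p$gain)
  y <- conv_fw(x, wsw, p$b, stride, pad)
  list(y = y, x = as_batch(x), wsw = wsw, stride = stride, pad = pad)
}

conv_ws_bw <- function(cache, p, dy) {
  g <- conv_bw(cache$x, cache$wsw, dy, cache$stride, cache$pad)
  ws_g <- standardize_weights_bw(p$w, p$gain, g$dw)
  list(dx = g$dx, grads = list(w = ws_g$dw, gain = ws_g$dgain, b = g$db))
}

# ---- activations ----------------------------------------------------------

relu_fw <- function(x) x * (x > 0)
relu_bw <- function(x, dy) dy * (x > 0)

# gamma-scaled ReLU used by the normalization-free blocks
act_fw <- function(x) GAMMA_RELU * (x * (x > 0))
act_bw <- function(x, dy) GAMMA_RELU * dy * (x > 0)

# ---- batch normalization (baseline ResNet family) ------------------------

bn_fw <- function(x, p, buf, train, momentum = 0.1, eps = 1e-5) {
  d <- dim(x)
  H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  xp <- aperm(x, c(1L, 2L, 4L, 3L))
  dim(xp) <- c(H * W * N, C)
  if (train) {
    mu <- colMeans(xp)
    v <- colMeans(xp * xp) - mu^2
    buf$rmean <- (1 - momentum) * buf$rmean + momentum * mu
    buf$rvar <- (1 - momentum) * buf$rvar + momentum * v
  } else {
    mu <- buf$rmean
    v <- buf$rvar
  }
  invstd <- 1 / sqrt(v + eps)
  xhat <- sweep(sweep(xp, 2L, mu), 2L, invstd, `*`)
  yp <- sweep(sweep(xhat, 2L, p$gamma, `*`), 2L, p$beta, `+`)
  dim(yp) <- c(H, W, N, C)
  y <- aperm(yp, c(1L, 2L, 4L, 3L))
  list(y = y, xhat = xhat, invstd = invstd, dims = d, train = train, buf = buf)
}

bn_bw <- function(cache, p, dy) {
  d <- cache$dims
  H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  dyp <- aperm(dy, c(1L, 2L, 4L, 3L))
  dim(dyp) <- c(H * W * N, C)
  xhat <- cache$xhat
  dgamma <- colSums(dyp * xhat)
  dbeta <- colSums(dyp)
  dxhat <- sweep(dyp, 2L, p$gamma, `*`)
  if (cache$train) {
    m1 <- colMeans(dxhat)
    m2 <- colMeans(dxhat * xhat)
    dxp <- sweep(sweep(dxhat, 2L, m1) - sweep(xhat, 2L, m2, `*`),
                 2L, cache$invstd, `*`)
  } else {
    dxp <- sweep(dxhat, 2L, cache$invstd, `*`)
  }
  dim(dxp) <- c(H, W, N, C)
  dx <- aperm(dxp, c(1L, 2L, 4L, 3L))
  list(dx = dx, grads = list(gamma = dgamma, beta = dbeta))
}

# ---- pooling and head -----------------------------------------------------

# batched global average pooling: (H, W, C, N) -> (C, N)
gap_fw <- function(x) {
  d <- dim(x)
  xm <- x
  dim(xm) <- c(d[1] * d[2], d[3] * d[4])
  matrix(colMeans(xm), d[3], d[4])
}

gap_bw <- function(dpool, dims) {
  scale <- 1 / (dims[1] * dims[2])
  dx <- array(rep(as.numeric(dpool) * scale, each = dims[1] * dims[2]), dims)
  dx
}

fc_fw <- function(pool, p) t(p$w %*% pool + p$b)  # (N, n_out)

fc_bw <- function(pool, p, dlogits) {
  dz <- t(dlogits)  # (n_out, N)
  list(dpool = t(p$w) %*% dz,
       grads = list(w = dz %*% t(pool), b = rowSums(dz)))
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

# mean cross-entropy and its gradient w.r.t. the logits
ce_loss <- function(logits, labels01) {
  n <- nrow(logits)
  p <- softmax_rows(logits)
  idx <- cbind(seq_len(n), labels01 + 1L)
  loss <- -mean(log(pmax(p[idx], 1e-12)))
  onehot <- matrix(0, n, ncol(logits))
  onehot[idx] <- 1
  list(loss = loss, dlogits = (p - onehot) / n, probs = p)
}

# ---- initialization -------------------------------------------------------

init_conv <- function(kh, kw, cin, cout, ws = TRUE) {
  fan <- kh * kw * cin
  w <- array(rnorm(kh * kw * cin * cout, sd = sqrt(2 / fan)), c(kh, kw, cin, cout))
  if (ws) list(w = w, gain = rep(1, cout), b = rep(0, cout))
  else list(w = w)
}

init_fc <- function(n_in, n_out) {
  list(w = matrix(rnorm(n_out * n_in, sd = 1 / sqrt(n_in)), n_out, n_in),
       b = rep(0, n_out))
}
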