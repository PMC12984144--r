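# Brute-force reference implementations used as independent oracles.
# All operate on single samples with explicit loops; they share no code with
# the package's compute paths.

# direct sliding-window convolution, (H, W, C) x (kh, kw, C, Cout)
oracle_conv <- function(x, w, b, stride = 1L, pad = 0L) {
  d <- dim(x); wd <- dim(w)
  Ho <- (d[1] + 2 * pad - wd[1]) %/% stride + 1L
  Wo <- (d[2] + 2 * pad - wd[2]) %/% stride + 1L
  xp <- array(0, c(d[1] + 2 * pad, d[2] + 2 * pad, d[3]))
  xp[pad + seq_len(d[1]), pad + seq_len(d[2]), ] <- x
  y <- array(0, c(Ho, Wo, wd[4]))
  for (o in seq_len(wd[4])) {
    wo <- array(w[, , , o], wd[1:3])
    for (i in seq_len(Ho)) for (j in seq_len(Wo)) {
      patch <- xp[(i - 1L) * stride + seq_len(wd[1]),
                  (j - 1L) * stride + seq_len(wd[2]), , drop = FALSE]
      y[i, j, o] <- sum(patch * wo) + b[o]
    }
  }
  y
}

# per-channel spatial mean/max by explicit double loop
oracle_descriptors <- function(xr) {
  d <- dim(xr)
  avg <- numeric(d[3]); mx <- rep(-Inf, d[3])
  for (c in seq_len(d[3])) {
    s <- 0
    for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
      s <- s + xr[i, j, c]
      if (xr[i, j, c] > mx[c]) mx[c] <- xr[i, j, c]
    }
    avg[c] <- s / (d[1] * d[2])
  }
  list(avg = avg, max = mx)
}

oracle_channel_attention <- function(avg, mx, w0, w1) {
  za <- w1 %*% pmax(w0 %*% avg, 0)
  zm <- w1 %*% pmax(w0 %*% mx, 0)
  as.numeric(1 / (1 + exp(-(za + zm))))
}

oracle_spatial_attention <- function(xr, wsp, bsp) {
  d <- dim(xr)
  s <- array(0, c(d[1], d[2], 2L))
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
    s[i, j, 1L] <- mean(xr[i, j, ])
    s[i, j, 2L] <- max(xr[i, j, ])
  }
  a <- oracle_conv(s, wsp, bsp, stride = 1L, pad = 3L)
  1 / (1 + exp(-a[, , 1L]))
}

# full hybrid attention by composing the oracles above
oracle_hybrid <- function(x, ap) {
  xr <- oracle_conv(x, ap$reduce$w, ap$reduce$b)
  dsc <- oracle_descriptors(xr)
  mc <- oracle_channel_attention(dsc$avg, dsc$max, ap$w0, ap$w1)
  ms <- oracle_spatial_attention(xr, ap$spatial$w, ap$spatial$b)
  d <- dim(xr)
  ych <- xr
  ysp <- xr
  for (c in seq_len(d[3])) {
    ych[, , c] <- xr[, , c] * mc[c]
    ysp[, , c] <- xr[, , c] * ms
  }
  out <- array(0, c(d[1], d[2], 2L * d[3]))
  out[, , seq_len(d[3])] <- ych
  out[, , d[3] + seq_len(d[3])] <- ysp
  out
}

# confusion counts by explicit loop
oracle_confusion <- function(labels, preds) {
  tp <- fp <- fn <- tn <- 0L
  for (i in seq_along(labels)) {
    if (labels[i] == 1 && preds[i] == 1) tp <- tp + 1L
    else if (labels[i] == 0 && preds[i] == 1) fp <- fp + 1L
    else if (labels[i] == 1 && preds[i] == 0) fn <- fn + 1L
    else tn <- tn + 1L
  }
  list(tp = tp, fp = fp, fn = fn, tn = tn)
}

# Mann-Whitney AUC over all positive-negative pairs, ties counting 1/2
oracle_auc <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  s <- 0
  for (p in pos) for (q in neg) {
    s <- s + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  s / (length(pos) * length(neg))
}

# random attention parameters with non-degenerate weights
random_attention_params <- function(channels, r = 4L, r2 = 4L) {
  ap <- attention_params(channels, r = r, r2 = r2)
  ap
}

# small helper: a tiny assembled model reused across tests
tiny_model <- function(family = "nf_resnet", attention = list(r = 4), seed = 11,
                       width = 0.0625, input_size = 32) {
  assemble_model(backbone_config(family, 26, width, input_size), attention,
                 seed = seed)
}

expect_finite <- function(x) expect_true(all(is.finite(x)))
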