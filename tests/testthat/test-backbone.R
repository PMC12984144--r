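# Backbone feature extractors: weight standardization, structure, and
# normalization-free signal propagation.

test_that("weight standardization centres, rescales and preserves the input", {
  # hand-computed: row (1, -1), gain 1, fan-in 2 -> (1, -1)/sqrt(2)
  ws <- standardize_weights(matrix(c(1, -1), 1, 2))
  expect_equal(as.numeric(ws), c(1, -1) / sqrt(2), tolerance = 1e-4)
  # constant kernels standardize to zero via the eps guard
  expect_equal(as.numeric(standardize_weights(matrix(3, 1, 8))), rep(0, 8))
  set.seed(21)
  w <- array(rnorm(8 * 4 * 3 * 3, mean = 2), c(3, 3, 4, 8))
  w0 <- w + 0
  ws <- standardize_weights(w, gain = runif(8, 0.5, 2))
  m <- matrix(ws, 9 * 4, 8)
  expect_lt(max(abs(colMeans(m))), 1e-6)
  expect_identical(w, w0)  # input unchanged
})

test_that("standardization gradient matches finite differences and is finite", {
  set.seed(22)
  w <- array(rnorm(2 * 3 * 3 * 4), c(3, 3, 2, 4))
  gain <- runif(4, 0.5, 2)
  dws <- array(rnorm(length(w)), dim(w))
  g <- fundusnet:::standardize_weights_bw(w, gain, dws)
  expect_finite(g$dw)
  expect_finite(g$dgain)
  h <- 1e-6
  for (i in sample(length(w), 10)) {
    wp <- w; wp[i] <- wp[i] + h
    wm <- w; wm[i] <- wm[i] - h
    num <- (sum(standardize_weights(wp, gain) * dws) -
            sum(standardize_weights(wm, gain) * dws)) / (2 * h)
    expect_equal(g$dw[i], num, tolerance = 1e-4)
  }
})

test_that("stage layouts reproduce the advertised depths and strides", {
  for (d in c(26, 50, 101)) {
    cfg <- backbone_config("nf_resnet", d, 0.125, 64)
    # layers = stem conv + 3 convs per bottleneck + final fc
    expect_equal(1L + 3L * sum(cfg$blocks_per_stage) + 1L, d)
  }
  expect_error(backbone_config("nf_resnet", 34), "unsupported depth")
})

test_that("feature maps have stride-32 spatial size and the configured width", {
  bb <- build_backbone(backbone_config("nf_resnet", 26, 0.125, 64), seed = 23)
  f <- extract_features(bb, array(runif(64 * 64 * 3), c(64, 64, 3)))
  expect_equal(dim(f), c(2L, 2L, 256L, 1L))
  bb50 <- build_backbone(backbone_config("nf_resnet", 50, 1, 224), seed = 24)
  f50 <- extract_features(bb50, array(runif(224 * 224 * 3), c(224, 224, 3)))
  expect_equal(dim(f50), c(7L, 7L, 2048L, 1L))
  expect_error(extract_features(bb, array(0, c(64, 64, 4))), "3 channels")
})

test_that("the NF family has zero normalization layers and the BN family does not", {
  nf <- build_backbone(backbone_config("nf_resnet", 26, 0.0625, 32), seed = 25)
  bn <- build_backbone(backbone_config("resnet", 26, 0.0625, 32), seed = 25)
  expect_equal(fundusnet:::count_norm_layers(nf), 0L)
  expect_gt(fundusnet:::count_norm_layers(bn), 0L)
})

test_that("NF features are batch-composition independent; training-mode BN is not", {
  set.seed(26)
  imgs <- array(runif(32 * 32 * 3 * 8), c(32, 32, 3, 8))
  nf <- build_backbone(backbone_config("nf_resnet", 26, 0.0625, 32), seed = 27)
  alone <- extract_features(nf, imgs[, , , 1])
  batch <- extract_features(nf, imgs)
  expect_lt(max(abs(alone[, , , 1] - batch[, , , 1])), 1e-6)
  # identical calls are bitwise stable
  expect_identical(extract_features(nf, imgs), batch)
  # negative control: batch statistics couple the samples in training mode
  bn <- build_backbone(backbone_config("resnet", 26, 0.0625, 32), seed = 27)
  f_alone <- fundusnet:::backbone_fw(bn, imgs[, , , 1, drop = FALSE],
                                     train = TRUE, keep = FALSE)$features
  f_batch <- fundusnet:::backbone_fw(bn, imgs, train = TRUE, keep = FALSE)$features
  expect_gt(max(abs(f_alone[, , , 1] - f_batch[, , , 1])), 1e-6)
})

test_that("signal variance stays within a factor of 4 across stages at initialization", {
  set.seed(28)
  bb <- build_backbone(backbone_config("nf_resnet", 26, 0.125, 64), seed = 29)
  x <- array(rnorm(64 * 64 * 3 * 4), c(64, 64, 3, 4))
  out <- fundusnet:::backbone_fw(bb, x, keep = TRUE)
  v_in <- stats::var(as.numeric(x))
  for (s in 1:4) {
    stage_out <- if (s < 4) out$cache$blocks[[s + 1]][[1]]$x_in else out$cache$pre_act_in
    v <- stats::var(as.numeric(stage_out))
    expect_gt(v, v_in / 4)
    expect_lt(v, v_in * 4)
  }
  expect_finite(out$features)
})

test_that("gradients through standardized convolutions are finite after one step", {
  m <- tiny_model(seed = 30)
  x <- array(runif(32 * 32 * 3 * 2), c(32, 32, 3, 2))
  fwd <- fundusnet:::model_fw(m, x, keep = TRUE)
  cl <- fundusnet:::ce_loss(fwd$logits, c(0L, 1L))
  bwd <- fundusnet:::model_bw(m, fwd, cl$dlogits)
  g <- fundusnet:::flatten_params(bwd$grads)
  expect_finite(g)
  expect_gt(max(abs(g)), 0)
})
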