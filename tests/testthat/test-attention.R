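# Hybrid channel + spatial attention block.

test_that("pointwise reduction divides channels by r and rejects non-divisible C", {
  set.seed(1)
  ap <- attention_params(8, r = 4)
  x <- array(rnorm(5 * 6 * 8), c(5, 6, 8))
  xr <- reduce_channels(x, ap)
  expect_equal(dim(xr), c(5L, 6L, 2L))
  expect_error(attention_params(10, r = 4), "not divisible")
  expect_error(reduce_channels(array(0, c(2, 2, 4)), ap), "channels")
})

test_that("reduction with an averaging kernel returns the per-pixel channel mean", {
  set.seed(2)
  C <- 8
  ap <- attention_params(C, r = 8)
  ap$reduce$w[] <- 1 / C
  ap$reduce$b[] <- 0
  x <- array(rnorm(4 * 4 * C), c(4, 4, C))
  xr <- reduce_channels(x, ap)
  expect_equal(xr[, , 1], apply(x, c(1, 2), mean), tolerance = 1e-12)
})

test_that("reduction matches the explicit pointwise-convolution oracle", {
  set.seed(3)
  ap <- attention_params(4, r = 4)
  x <- array(rnorm(2 * 2 * 4), c(2, 2, 4))
  expect_equal(reduce_channels(x, ap),
               oracle_conv(x, ap$reduce$w, ap$reduce$b),
               tolerance = 1e-6)
})

test_that("channel descriptors are the spatial mean and max per channel", {
  x <- array(0, c(2, 2, 2))
  x[, , 1] <- matrix(c(0, 2, 1, 3), 2, 2)  # values {0,1,2,3}
  x[, , 2] <- 5
  d <- channel_descriptors(x)
  expect_equal(d$avg, c(1.5, 5))
  expect_equal(d$max, c(3, 5))
  set.seed(4)
  xr <- array(rnorm(5 * 5 * 3), c(5, 5, 3))
  o <- oracle_descriptors(xr)
  got <- channel_descriptors(xr)
  expect_equal(got$avg, o$avg, tolerance = 1e-7)
  expect_equal(got$max, o$max, tolerance = 1e-7)
})

test_that("channel attention reproduces closed-form sigmoid values", {
  ap <- attention_params(4, r = 4)  # C' = 1, hidden clamps to 1
  ap$w0[] <- 0
  ap$w1[] <- 0
  expect_equal(channel_attention(1, 1, ap), 0.5)
  ap$w0[] <- 1
  ap$w1[] <- 1
  # sigmoid(1 + 1)
  expect_equal(channel_attention(1, 1, ap), 1 / (1 + exp(-2)), tolerance = 1e-9)
})

test_that("channel attention matches the explicit MLP oracle and stays in (0,1)", {
  set.seed(5)
  for (rep in 1:5) {
    ap <- attention_params(32, r = 4, r2 = 4)  # C' = 8, hidden 2
    avg <- rnorm(8)
    mx <- rnorm(8)
    got <- channel_attention(avg, mx, ap)
    expect_equal(got, oracle_channel_attention(avg, mx, ap$w0, ap$w1),
                 tolerance = 1e-6)
    expect_true(all(got > 0 & got < 1))
  }
  expect_error(channel_attention(rnorm(3), rnorm(3), attention_params(32, 4)),
               "descriptor length")
})

test_that("spatial attention preserves spatial shape and matches the convolution oracle", {
  set.seed(6)
  ap <- attention_params(64, r = 4)
  xr <- array(rnorm(7 * 7 * 16), c(7, 7, 16))
  ms <- spatial_attention(xr, ap)
  expect_equal(dim(ms), c(7L, 7L))
  # zero kernel -> sigmoid(0) = 0.5 everywhere
  ap0 <- ap
  ap0$spatial$w[] <- 0
  ap0$spatial$b[] <- 0
  expect_equal(spatial_attention(xr, ap0), matrix(0.5, 7, 7))
  # direct sliding-window oracle on a 2-channel 9x9 input
  ap2 <- attention_params(8, r = 4)
  xr2 <- array(rnorm(9 * 9 * 2), c(9, 9, 2))
  expect_equal(spatial_attention(xr2, ap2),
               oracle_spatial_attention(xr2, ap2$spatial$w, ap2$spatial$b),
               tolerance = 1e-6)
})

test_that("zero-parameter attention returns 0.5 maps and halves the reduced input", {
  set.seed(7)
  ap <- attention_params(8, r = 4, r2 = 2)
  ap$w0[] <- 0; ap$w1[] <- 0
  ap$spatial$w[] <- 0; ap$spatial$b[] <- 0
  x <- array(rnorm(4 * 4 * 8), c(4, 4, 8))
  xr <- reduce_channels(x, ap)
  out <- hybrid_forward(x, ap)
  expect_equal(dim(out), c(4L, 4L, 4L))
  expect_equal(out[, , 1:2], 0.5 * xr, tolerance = 1e-12)
  expect_equal(out[, , 3:4], 0.5 * xr, tolerance = 1e-12)
})

test_that("hybrid output has 2C/r channels and equals the composed oracle", {
  set.seed(8)
  cases <- list(c(C = 8, r = 4), c(C = 16, r = 2), c(C = 16, r = 8))
  for (cs in cases) {
    C <- cs[["C"]]; r <- cs[["r"]]
    ap <- attention_params(C, r = r, r2 = 4)
    x <- array(rnorm(8 * 8 * C), c(8, 8, C))
    out <- hybrid_forward(x, ap)
    expect_equal(dim(out)[3], 2L * C %/% r)
    expect_equal(out, oracle_hybrid(x, ap), tolerance = 1e-6)
  }
})

test_that("attention maps stay strictly inside (0,1) and the block is deterministic", {
  set.seed(9)
  ap <- attention_params(16, r = 4, r2 = 2)
  x <- array(rnorm(6 * 5 * 16, sd = 5), c(6, 5, 16))
  xr <- reduce_channels(x, ap)
  mc <- channel_attention(channel_descriptors(xr)$avg, channel_descriptors(xr)$max, ap)
  ms <- spatial_attention(xr, ap)
  expect_true(all(mc > 0 & mc < 1))
  expect_true(all(ms > 0 & ms < 1))
  expect_identical(hybrid_forward(x, ap), hybrid_forward(x, ap))
})

test_that("spatial attention is invariant to channel permutations of the reduced map", {
  set.seed(10)
  ap <- attention_params(24, r = 4)
  xr <- array(rnorm(5 * 5 * 6), c(5, 5, 6))
  perm <- sample(6)
  expect_equal(spatial_attention(xr, ap), spatial_attention(xr[, , perm], ap),
               tolerance = 1e-12)
})
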