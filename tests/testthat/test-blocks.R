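test_that("convolution cost formulas match direct evaluation", {
  expect_equal(standard_conv_cost(conv_spec(3, 3, 32)), 864)
  expect_equal(standard_conv_cost(conv_spec(1, 128, 32)), 4096)
  expect_equal(standard_conv_cost(conv_spec(3, 128, 32)), 36864)
  expect_equal(separable_conv_cost(conv_spec(3, 128, 32)), 5248)
  expect_equal(separable_conv_cost(conv_spec(3, 32, 32)), 1312)
  # cost ratio collapses to 1/C_out + 1/k^2
  ratio <- separable_conv_cost(conv_spec(3, 128, 32)) /
    standard_conv_cost(conv_spec(3, 128, 32))
  expect_equal(ratio, 1 / 32 + 1 / 9)
  expect_error(standard_conv_cost(conv_spec(3, 16, 16, depthwise = TRUE)),
               "dense convolutions")
  expect_error(conv_spec(3, 16, 8, depthwise = TRUE), "out_channels")
})

test_that("separable factorization is cheaper whenever it can be", {
  set.seed(11)
  for (i in 1:50) {
    k <- sample(2:7, 1)
    ci <- sample(1:256, 1); co <- sample(2:256, 1)
    sp <- conv_spec(k, ci, co)
    expect_lt(separable_conv_cost(sp), standard_conv_cost(sp))
  }
})

test_that("1-D atrous convolution matches hand evaluation", {
  expect_equal(atrous_conv_1d(1:5, c(1, 1, 1), 1), c(6, 9, 12))
  expect_equal(atrous_conv_1d(1:5, c(1, 1, 1), 2), 9)
  # identity kernel passes the signal through at any rate
  x <- rnorm(20)
  for (r in c(1, 3, 6)) {
    y <- atrous_conv_1d(x, c(1, 0, 0), r)
    expect_equal(y, x[seq_along(y)])
  }
  expect_error(atrous_conv_1d(1:5, c(1, 1, 1), 3), "shorter than")
})

test_that("squeeze computes per-channel spatial means", {
  expect_equal(se_squeeze(feature_map(array(3.5, c(4, 5, 6)))), rep(3.5, 6))
  expect_equal(se_squeeze(matrix(c(1, 3, 2, 4), 2, 2)), 2.5)
  expect_equal(se_squeeze(array(0, c(3, 3, 4))), rep(0, 4))
})

test_that("SE block gates channels through the bottleneck", {
  cfg <- se_config(channels = 8L, squeeze_units = 2L)
  fm <- feature_map(array(rnorm(4 * 4 * 8), c(4, 4, 8)))
  # zero weights: sigmoid(0) = 1/2 everywhere
  out <- se_block(fm, cfg, se_weights(cfg, "zeros"))
  expect_equal(unclass(out), unclass(fm) * 0.5, ignore_attr = TRUE)
  expect_equal(attr(out, "gates"), rep(0.5, 8))
  # multiplicative gating: zero input stays zero for any weights
  w <- se_weights(cfg, "random", seed = 4)
  z <- se_block(feature_map(array(0, c(4, 4, 8))), cfg, w)
  expect_true(all(z == 0))
  # gates equal a hand-rolled squeeze -> affine -> rectify -> affine -> sigmoid
  g <- attr(se_block(fm, cfg, w), "gates")
  s <- apply(unclass(fm), 3, mean)
  h <- pmax(as.vector(s %*% w$W1) + w$b1, 0)
  expect_equal(g, 1 / (1 + exp(-(as.vector(h %*% w$W2) + w$b2))),
               tolerance = 1e-12)
  expect_true(all(g > 0 & g < 1))
  expect_error(se_block(feature_map(array(1, c(2, 2, 5))), cfg, w),
               "channels")
})

test_that("pyramid pooling preserves spatial dims and fuses 4 branches", {
  cfg <- aspp_config(in_channels = 8L, branch_channels = 4L,
                     fuse_channels = 8L)
  fm <- feature_map(array(rnorm(14 * 14 * 8), c(14, 14, 8)))
  w <- aspp_weights(cfg, "random", seed = 2)
  out <- aspp(fm, cfg, w)
  expect_shape(out, c(14, 14, 8))
  # all-zero branch kernels: output is the fuse bias, constant per channel
  wz <- aspp_weights(cfg, "zeros")
  wz$fuse$b <- rnorm(8)
  outz <- aspp(fm, cfg, wz)
  for (ch in 1:8) expect_equal(unique(as.vector(outz[, , ch])),
                               wz$fuse$b[ch])
  expect_error(aspp(feature_map(array(1, c(5, 5, 3))), cfg, w), "channels")
  expect_error(aspp_config(dilation_rates = c(3, 1)), "increasing")
})

test_that("dilated branches equal dense convolution with zero-inserted kernels", {
  # 2-D dilation equivalence on single-channel maps, checked against a
  # loop-based dense convolution of the expanded kernel (valid region)
  set.seed(21)
  for (rep_i in 1:10) for (r in c(1, 3, 6)) {
    n <- (3 - 1) * r + 1 + sample(0:3, 1)   # just covers the kernel span
    x <- matrix(rnorm(n * n), n, n)
    kern <- matrix(rnorm(9), 3, 3)
    W <- array(kern, c(3, 3, 1, 1))
    got <- pneunet:::nn_conv2d(array(x, c(n, n, 1, 1)), W, 0,
                               dilation = r)$out
    want_valid <- oracle_conv2d_valid(x, dilate_kernel(kern, r))
    pad <- (nrow(dilate_kernel(kern, r)) - 1) / 2
    centre <- (pad + 1):(n - pad)
    expect_equal(as.vector(got[centre, centre, 1, 1]),
                 as.vector(want_valid), tolerance = 1e-6)
  }
})

test_that("1-D atrous oracle agrees with the 2-D engine row-wise", {
  set.seed(33)
  for (r in c(1, 3, 6)) {
    n <- 2 * r + 7
    x <- rnorm(n)
    wv <- rnorm(3)
    # a (1 x k) kernel applied to a single-row map is the 1-D operation
    W <- array(0, c(3, 3, 1, 1)); W[2, , 1, 1] <- wv
    row_map <- array(0, c(3 + 2 * r, n, 1, 1))  # tall enough for same-pad
    row_map[r + 2, , 1, 1] <- x
    got <- pneunet:::nn_conv2d(row_map, W, 0, dilation = r)$out[r + 2, , 1, 1]
    want <- atrous_conv_1d(x, wv, r)
    pad <- r  # same-padding offset of the valid segment
    expect_equal(got[(pad + 1):(pad + length(want))], want, tolerance = 1e-9)
  }
})

test_that("learnable pooling is an attention-weighted spatial sum", {
  cfg <- learnable_pooling_config(in_channels = 6L, hidden_channels = 6L)
  wz <- learnable_pooling_weights(cfg, "zeros")
  fm <- feature_map(array(rnorm(3 * 5 * 6), c(3, 5, 6)))
  # zero weights: A = 1/2 everywhere, pooled = half the spatial sum
  p <- learnable_pool(fm, cfg, wz)
  expect_equal(as.vector(p), 0.5 * apply(unclass(fm), 3, sum))
  expect_true(all(attr(p, "attention") == 0.5))
  expect_shape(attr(p, "attention"), c(3, 5))
  # ones on a 2x2 grid: 4 positions x 1/2
  p2 <- learnable_pool(feature_map(array(1, c(2, 2, 6))), cfg, wz)
  expect_equal(as.vector(p2), rep(2, 6))
  # single spatial position: pooled = value * sigmoid(pre-map)
  w <- learnable_pooling_weights(cfg, "random", seed = 8)
  fm1 <- feature_map(array(rnorm(6), c(1, 1, 6)))
  v <- as.vector(fm1)
  pre <- drop((v %*% w$W1 + w$b1) %*% w$W2) + w$b2
  expect_equal(as.vector(learnable_pool(fm1, cfg, w)),
               v * (1 / (1 + exp(-pre))))
  # attention strictly inside (0,1); normalized variant divides by sum(A)
  p3 <- learnable_pool(fm, cfg, w)
  A <- attr(p3, "attention")
  expect_true(all(A > 0 & A < 1))
  expect_equal(as.vector(learnable_pool(fm, cfg, w, normalize = TRUE)),
               as.vector(p3) / sum(A))
})

test_that("global average pooling equals the squeeze on any input", {
  expect_equal(gap_pool(feature_map(array(7, c(3, 3, 2)))), c(7, 7))
  expect_equal(gap_pool(matrix(c(0, 4, 2, 6), 2, 2)), 3)
  set.seed(5)
  fm <- feature_map(array(rnorm(6 * 7 * 3), c(6, 7, 3)))
  expect_equal(gap_pool(fm), se_squeeze(fm))
})

test_that("feature maps reject invalid input", {
  expect_error(feature_map(array(c(1, NA), c(1, 1, 2))), "finite")
  expect_error(feature_map(1:3), "3-D")
})
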