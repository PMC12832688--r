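test_that("layer parameter arithmetic reproduces every published count", {
  expect_equal(count_parameters(list(kind = "conv", kernel = 3,
                                     in_channels = 3, out_channels = 32)),
               896)
  expect_equal(count_parameters(list(kind = "se_block", channels = 128,
                                     squeeze_units = 8)), 2184)
  expect_equal(count_parameters(list(kind = "depthwise_conv", kernel = 3,
                                     channels = 128)), 1280)
  expect_equal(count_parameters(list(kind = "conv", kernel = 1,
                                     in_channels = 128, out_channels = 32)),
               4128)
  expect_equal(count_parameters(list(kind = "conv", kernel = 3,
                                     in_channels = 128, out_channels = 32)),
               36896)
  expect_equal(count_parameters(list(kind = "conv", kernel = 1,
                                     in_channels = 128,
                                     out_channels = 128)), 16512)
  expect_equal(count_parameters(list(kind = "learnable_pool",
                                     in_channels = 128,
                                     hidden_channels = 128)), 16641)
  expect_equal(count_parameters(list(kind = "dense", in_channels = 128,
                                     out_channels = 1)), 129)
  expect_equal(count_parameters(list(kind = "batch_norm", channels = 32)),
               64)
  expect_equal(count_parameters(list(kind = "dropout")), 0)
  expect_error(count_parameters(list(kind = "transformer")), "unknown")
})

test_that("the assembled graph audits to the published layer counts", {
  net <- build_pneunet(pneunet_config(), seed = 1)
  pr <- param_report(net)
  cnt <- function(layer) pr$params[pr$layer == layer]
  expect_equal(cnt("stem"), 896L)
  expect_equal(cnt("se"), 2184L)
  expect_equal(cnt("down_dw"), 1280L)
  expect_equal(cnt("aspp_pointwise"), 4128L)
  for (r in c(1, 3, 6))
    expect_equal(cnt(sprintf("aspp_rate%d", r)), 36896L)
  expect_equal(cnt("aspp_fuse"), 16512L)
  expect_equal(cnt("lpool"), 16641L)
  expect_equal(cnt("head"), 129L)
  # report conserves its own total
  expect_equal(attr(pr, "total"), sum(pr$params))
  # counts from the live arrays agree with the declarative arithmetic
  expect_equal(cnt("stem"),
               count_parameters(list(kind = "conv", kernel = 3,
                                     in_channels = 3, out_channels = 32)))
})

test_that("the ablation graph swaps the pooling head for parameter-free GAP", {
  gap <- build_pneunet(pneunet_config(pooling_mode = "gap"), seed = 1)
  pr <- param_report(gap)
  expect_false("lpool" %in% pr$layer)
  full <- param_report(build_pneunet(pneunet_config(), seed = 1))
  expect_equal(attr(full, "total") - attr(pr, "total"), 16641L)
})

test_that("stage shapes match the published architecture table", {
  net <- build_pneunet(pneunet_config(), seed = 1)
  sh <- stage_shapes(net)
  expect_equal(sh$input, c(224L, 224L, 3L))
  expect_equal(sh$stem, c(224L, 224L, 32L))
  expect_equal(sh$concat, c(224L, 224L, 128L))
  expect_equal(sh$se, c(224L, 224L, 128L))
  expect_equal(sh$down, c(112L, 112L, 128L))
  expect_equal(sh$aspp_fuse, c(112L, 112L, 128L))
  expect_equal(sh$pooled, 128L)
  expect_equal(sh$output, 1L)
})

test_that("a forward pass realizes the declared stage shapes", {
  # audited on a reduced input; the spatial arithmetic (same padding,
  # ceiling halving at stride 2) is size-independent
  net <- build_pneunet(pneunet_config(input_height = 20L,
                                      input_width = 20L), seed = 2)
  X <- array(rnorm(20 * 20 * 2 * 3), c(20, 20, 2, 3))
  p <- pneunet_forward(net, X)
  expect_length(p, 2)
  expect_true(all(p > 0 & p < 1))
  expect_shape(net$acts$stem, c(20, 20, 2, 32))
  expect_shape(net$acts$concat, c(20, 20, 2, 128))
  expect_shape(net$acts$se, c(20, 20, 2, 128))
  expect_shape(net$acts$down, c(10, 10, 2, 128))
  expect_shape(net$acts$aspp_fuse, c(10, 10, 2, 128))
  expect_shape(net$acts$attention, c(10, 10, 2))
  # odd input halves with ceiling
  net21 <- build_pneunet(pneunet_config(input_height = 21L,
                                        input_width = 21L), seed = 2)
  pneunet_forward(net21, array(0, c(21, 21, 1, 3)))
  expect_shape(net21$acts$down, c(11, 11, 1, 128))
})

test_that("a default-sized forward pass realizes the published shapes", {
  net <- build_pneunet(pneunet_config(), seed = 4)
  p <- pneunet_forward(net, array(0.5, c(224, 224, 1, 3)))
  expect_true(p > 0 && p < 1)
  expect_shape(net$acts$stem, c(224, 224, 1, 32))
  expect_shape(net$acts$concat, c(224, 224, 1, 128))
  expect_shape(net$acts$se, c(224, 224, 1, 128))
  expect_shape(net$acts$down, c(112, 112, 1, 128))
  expect_shape(net$acts$aspp_fuse, c(112, 112, 1, 128))
  expect_shape(net$acts$attention, c(112, 112, 1))
})

test_that("an all-zero image yields a finite probability in (0, 1)", {
  net <- build_pneunet(pneunet_config(input_height = 16L,
                                      input_width = 16L), seed = 3)
  p <- pneunet_forward(net, array(0, c(16, 16, 1, 3)))
  expect_true(is.finite(p) && p > 0 && p < 1)
  expect_error(pneunet_forward(net, array(0, c(16, 16, 1, 2))), "channels")
})

test_that("builds and forwards are reproducible from the seed", {
  cfg <- pneunet_config(input_height = 12L, input_width = 12L)
  n1 <- build_pneunet(cfg, seed = 7)
  n2 <- build_pneunet(cfg, seed = 7)
  expect_identical(n1$params, n2$params)
  X <- array(rnorm(12 * 12 * 2 * 3), c(12, 12, 2, 3))
  expect_identical(pneunet_forward(n1, X), pneunet_forward(n2, X))
  n3 <- build_pneunet(cfg, seed = 8)
  expect_false(identical(n1$params$stem$W, n3$params$stem$W))
})

test_that("checkpoints round-trip bit-identically through disk", {
  cfg <- pneunet_config(input_height = 12L, input_width = 12L)
  net <- build_pneunet(cfg, seed = 9)
  X <- array(rnorm(12 * 12 * 2 * 3), c(12, 12, 2, 3))
  p0 <- pneunet_forward(net, X)
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(pneunet_checkpoint(net, 5L, 0.31), path)
  expect_true(file.exists(paste0(path, ".json")))
  ck <- load_checkpoint(path)
  expect_equal(ck$best_epoch, 5L)
  net2 <- net_from_checkpoint(ck)
  expect_identical(pneunet_forward(net2, X), p0)
  expect_error(load_checkpoint(file.path(tempdir(), "missing.rds")),
               "exist")
})

test_that("complexity rows use the two cost formulas", {
  cx <- complexity_report(build_pneunet(pneunet_config(), seed = 1))
  expect_equal(cx$standard_macs[cx$layer == "stem"], 864)
  expect_equal(cx$separable_macs[cx$layer == "ds1"], 1312)
  sep <- cx[!is.na(cx$separable_macs), ]
  expect_true(all(sep$separable_macs < sep$standard_macs))
})

test_that("configuration invariants are enforced", {
  expect_error(pneunet_config(stem_filters = 16L), "128")
  expect_error(pneunet_config(dropout_rate = 1), "dropout_rate")
  cfg <- pneunet_config(fusion_branches = 4L, stem_filters = 32L)
  expect_equal(cfg$pooling_mode, "learnable")
})
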