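# Assembly of the full network, its forward and reverse passes, and the
# per-layer parameter/complexity auditors.
#
# Topology (output shapes for the 224 x 224 x 3 default):
#   stem 3x3 conv (32 ch, BN, ReLU)                       224 x 224 x 32
#   3 sequential depthwise-separable blocks, 32 ch each
#     (depthwise 3x3 + BN + ReLU, pointwise 1x1 + BN + ReLU, dropout)
#   concat of stem output + the three block outputs       224 x 224 x 128
#   squeeze-and-excitation gate (bottleneck 8)            224 x 224 x 128
#   depthwise 3x3 stride-2 downsample (BN, ReLU)          112 x 112 x 128
#   pyramid pooling: 1x1 + 3x3 dilated at rates 1/3/6,
#     each to 32 ch (BN, ReLU), concat, 1x1 fuse to 128   112 x 112 x 128
#   learnable pooling (or GAP in ablation mode)           128-vector
#   dropout, dense 128 -> 1, sigmoid                      probability

#' Architecture configuration
#'
#' @param input_height,input_width Input spatial size (default 224).
#' @param input_channels Input channels (default 3; grayscale inputs are
#'   replicated across the three planes by [preprocess()]).
#' @param stem_filters Channels of the stem convolution and of each
#'   depthwise-separable block (default 32).
#' @param fusion_branches Number of tensors concatenated after the feature-
#'   fusion stage: the stem plus `fusion_branches - 1` sequential blocks.
#'   `fusion_branches * stem_filters` must equal 128.
#' @param pooling_mode `"learnable"` (trainable spatial attention, the
#'   default) or `"gap"` (global average pooling, the ablation).
#' @param dropout_rate Dropout rate after each separable block and before
#'   the classifier head (default 0.3).
#' @param se_squeeze_units Bottleneck width of the channel-attention block.
#' @param dilation_rates Dilation rates of the pyramid-pooling branches.
#' @return A list with class `"pneunet_config"`.
#' @export
pneunet_config <- function(input_height = 224L, input_width = 224L,
                           input_channels = 3L, stem_filters = 32L,
                           fusion_branches = 4L,
                           pooling_mode = c("learnable", "gap"),
                           dropout_rate = 0.3, se_squeeze_units = 8L,
                           dilation_rates = c(1L, 3L, 6L)) {
  pooling_mode <- match.arg(pooling_mode)
  if (fusion_branches * stem_filters != 128L)
    stopf("fusion_branches * stem_filters must equal 128 (got %d * %d)",
          fusion_branches, stem_filters)
  if (dropout_rate < 0 || dropout_rate >= 1)
    stopf("dropout_rate must lie in [0, 1)")
  structure(list(input_height = as.integer(input_height),
                 input_width = as.integer(input_width),
                 input_channels = as.integer(input_channels),
                 stem_filters = as.integer(stem_filters),
                 fusion_branches = as.integer(fusion_branches),
                 pooling_mode = pooling_mode,
                 dropout_rate = dropout_rate,
                 se_squeeze_units = as.integer(se_squeeze_units),
                 dilation_rates = as.integer(dilation_rates)),
            class = "pneunet_config")
}

he_init <- function(dims, fan_in) {
  array(stats::rnorm(prod(dims), sd = sqrt(2 / fan_in)), dims)
}

#' Build the network
#'
#' Constructs the full graph with variance-scaling (fan-in) initial kernels,
#' zero biases and unit batch-norm scales. Two builds from the same seed
#' produce identical weights.
#'
#' @param cfg A [pneunet_config()].
#' @param seed Integer seed controlling weight initialization.
#' @return An environment of class `"pneunet"` holding `config`, `params`
#'   and batch-norm running statistics.
#' @export
build_pneunet <- function(cfg = pneunet_config(), seed = 1L) {
  stopifnot(inherits(cfg, "pneunet_config"))
  S <- cfg$stem_filters
  C <- cfg$fusion_branches * S   # fused channel count, 128 by default
  u <- cfg$se_squeeze_units
  Cb <- 32L                      # pyramid branch width
  net <- new.env(parent = emptyenv())
  net$config <- cfg
  with_seed(seed, {
    p <- list()
    p$stem <- list(W = he_init(c(3, 3, cfg$input_channels, S),
                               9 * cfg$input_channels), b = numeric(S))
    p$stem_bn <- list(gamma = rep(1, S), beta = numeric(S))
    for (i in seq_len(cfg$fusion_branches - 1L)) {
      p[[sprintf("ds%d_dw", i)]] <- list(W = he_init(c(3, 3, S), 9),
                                         b = numeric(S))
      p[[sprintf("ds%d_dw_bn", i)]] <- list(gamma = rep(1, S), beta = numeric(S))
      p[[sprintf("ds%d_pw", i)]] <- list(W = he_init(c(1, 1, S, S), S),
                                         b = numeric(S))
      p[[sprintf("ds%d_pw_bn", i)]] <- list(gamma = rep(1, S), beta = numeric(S))
    }
    p$se <- list(W1 = he_init(c(C, u), C), b1 = numeric(u),
                 W2 = he_init(c(u, C), u), b2 = numeric(C))
    p$down_dw <- list(W = he_init(c(3, 3, C), 9), b = numeric(C))
    p$down_bn <- list(gamma = rep(1, C), beta = numeric(C))
    p$aspp_pointwise <- list(W = he_init(c(1, 1, C, Cb), C), b = numeric(Cb))
    p$aspp_pointwise_bn <- list(gamma = rep(1, Cb), beta = numeric(Cb))
    for (r in cfg$dilation_rates) {
      p[[sprintf("aspp_rate%d", r)]] <- list(W = he_init(c(3, 3, C, Cb), 9 * C),
                                             b = numeric(Cb))
      p[[sprintf("aspp_rate%d_bn", r)]] <- list(gamma = rep(1, Cb),
                                                beta = numeric(Cb))
    }
    Ccat <- Cb * (1L + length(cfg$dilation_rates))
    p$aspp_fuse <- list(W = he_init(c(1, 1, Ccat, C), Ccat), b = numeric(C))
    p$aspp_fuse_bn <- list(gamma = rep(1, C), beta = numeric(C))
    if (cfg$pooling_mode == "learnable") {
      # attention bias starts at sigmoid^-1(1/(H'W')) so the initial map
      # integrates to ~1 and the pooled sum opens at the scale of the
      # global average it replaces; training grows it from there
      hw <- ceiling(cfg$input_height / 2) * ceiling(cfg$input_width / 2)
      p$lpool <- list(W1 = he_init(c(C, C), C) * 0.1, b1 = numeric(C),
                      W2 = he_init(c(C, 1), C) * 0.1,
                      b2 = -log(hw - 1))
    }
    # classifier head starts at zero so the output begins at p = 0.5
    # regardless of the scale of the pooled features (the attention pooling
    # is an unnormalized spatial sum, so its outputs are O(H*W))
    p$head <- list(W = matrix(0, C, 1), b = 0)
    net$params <- p
  })
  net$bn_state <- list()
  for (nm in names(net$params)) {
    if (grepl("_bn$", nm)) {
      nc <- length(net$params[[nm]]$gamma)
      net$bn_state[[nm]] <- list(mean = numeric(nc), var = rep(1, nc))
    }
  }
  class(net) <- "pneunet"
  net
}

# Names of weight groups whose elements W/W1/W2 are kernels (L2-decayed).
kernel_elements <- function(params) {
  out <- list()
  for (g in names(params))
    for (el in intersect(names(params[[g]]), c("W", "W1", "W2")))
      out[[length(out) + 1L]] <- c(g, el)
  out
}

# Spatial stages whose activations/gradients Grad-CAM may target.
PNEUNET_STAGES <- c("stem", "concat", "se", "down", "aspp_fuse")

# conv -> BN -> ReLU helper used by the forward pass
fwd_cbr <- function(net, x, conv_name, training, depthwise = FALSE,
                    stride = 1L, dilation = 1L) {
  p <- net$params[[conv_name]]
  cv <- if (depthwise) nn_dwconv2d(x, p$W, p$b, stride = stride,
                                   dilation = dilation)
  else nn_conv2d(x, p$W, p$b, stride = stride, dilation = dilation)
  bn_name <- if (conv_name == "down_dw") "down_bn" else paste0(conv_name, "_bn")
  pb <- net$params[[bn_name]]
  bn <- nn_batchnorm(cv$out, pb$gamma, pb$beta, net$bn_state[[bn_name]],
                     training || isTRUE(net$.bn_refresh))
  net$bn_state[[bn_name]] <- bn$state
  rl <- nn_relu(bn$out)
  net$.cache[[conv_name]] <- list(conv = cv$cache, bn = bn$cache,
                                  relu = rl$cache, bn_name = bn_name,
                                  depthwise = depthwise)
  rl$out
}

#' Re-estimate batch-norm inference statistics
#'
#' Replaces the exponential-moving-average batch-norm statistics with exact
#' pooled moments computed from forward passes over `X` with the current
#' weights and dropout inactive (precise batch norm). In the short-run
#' regime the moving averages are noisy and collected under dropout, which
#' systematically shifts evaluation-mode activations; re-estimation aligns
#' inference statistics with the weights actually being evaluated.
#'
#' @param net A built network (modified in place).
#' @param X Batch tensor `(H, W, N, C)` to estimate from (typically the
#'   training set).
#' @param batch_size Forward-pass batch size.
#' @return The network, invisibly.
#' @export
refresh_bn_stats <- function(net, X, batch_size = 64L) {
  N <- dim(X)[3]
  acc <- list()
  net$.bn_refresh <- TRUE
  on.exit(net$.bn_refresh <- FALSE)
  for (start in seq(1L, N, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, N)
    pneunet_forward(net, X[, , idx, , drop = FALSE], training = FALSE)
    for (nm in names(net$.cache)) {
      cb <- net$.cache[[nm]]
      if (!is.list(cb) || is.null(cb$bn)) next
      n_b <- prod(cb$bn$d[1:3])
      a <- acc[[cb$bn_name]]
      if (is.null(a)) a <- list(n = 0, s1 = 0, s2 = 0)
      a$n <- a$n + n_b
      a$s1 <- a$s1 + n_b * cb$bn$mu
      a$s2 <- a$s2 + n_b * (cb$bn$v + cb$bn$mu^2)
      acc[[cb$bn_name]] <- a
    }
  }
  for (nm in names(acc)) {
    mu <- acc[[nm]]$s1 / acc[[nm]]$n
    net$bn_state[[nm]]$mean <- mu
    net$bn_state[[nm]]$var <- pmax(acc[[nm]]$s2 / acc[[nm]]$n - mu^2, 0)
  }
  invisible(net)
}

bwd_cbr <- function(net, conv_name, dy) {
  cc <- net$.cache[[conv_name]]
  dy <- nn_relu_bwd(cc$relu, dy)
  bn <- nn_batchnorm_bwd(cc$bn, dy)
  net$grads[[cc$bn_name]] <- list(gamma = bn$dgamma, beta = bn$dbeta)
  cv <- if (cc$depthwise) nn_dwconv2d_bwd(cc$conv, bn$dX)
  else nn_conv2d_bwd(cc$conv, bn$dX)
  net$grads[[conv_name]] <- list(W = cv$dW, b = cv$db)
  cv$dX
}

#' Forward pass
#'
#' @param net A network from [build_pneunet()] or [net_from_checkpoint()].
#' @param X Batched input, a 4-D array `(H, W, N, C_in)`; a single feature
#'   map `(H, W, C_in)` is promoted to a batch of one.
#' @param training Logical; enables dropout and batch-statistics mode (and
#'   caches every intermediate needed by [pneunet_backward()]).
#' @return Numeric vector of pneumonia probabilities, one per batch item.
#'   Stage activations are cached on the network for inspection.
#' @export
pneunet_forward <- function(net, X, training = FALSE) {
  cfg <- net$config
  if (length(dim(X)) == 3) dim(X) <- c(dim(X)[1:2], 1L, dim(X)[3])
  d <- dim(X)
  if (d[4] != cfg$input_channels)
    stopf("input has %d channels, the network expects %d", d[4],
          cfg$input_channels)
  net$.cache <- list(training = training)
  net$acts <- list()
  n_blocks <- cfg$fusion_branches - 1L
  S <- cfg$stem_filters; C <- cfg$fusion_branches * S

  s0 <- fwd_cbr(net, X, "stem", training)
  net$acts$stem <- s0
  outs <- vector("list", n_blocks)
  xin <- s0
  for (i in seq_len(n_blocks)) {
    h <- fwd_cbr(net, xin, sprintf("ds%d_dw", i), training, depthwise = TRUE)
    h <- fwd_cbr(net, h, sprintf("ds%d_pw", i), training)
    dr <- nn_dropout(h, cfg$dropout_rate, training)
    net$.cache[[sprintf("ds%d_drop", i)]] <- dr$cache
    outs[[i]] <- dr$out
    xin <- dr$out
  }
  dcc <- c(d[1], d[2], d[3], C)
  cc <- array(0, dcc)
  cc[, , , seq_len(S)] <- s0
  for (i in seq_len(n_blocks))
    cc[, , , i * S + seq_len(S)] <- outs[[i]]
  net$acts$concat <- cc

  # squeeze-and-excitation gating (per-sample channel gates)
  hw <- d[1] * d[2]
  sq <- colMeans(matrix(cc, hw, d[3] * C))          # (n, c) means
  sq <- matrix(sq, d[3], C)
  p <- net$params$se
  pre1 <- sq %*% p$W1 + rep(p$b1, each = d[3])
  h1 <- pmax(pre1, 0)
  g <- nn_sigmoid(h1 %*% p$W2 + rep(p$b2, each = d[3]))
  se_out <- cc * rep(as.vector(g), each = hw)
  net$.cache$se <- list(sq = sq, pre1 = pre1, h1 = h1, g = g, cc = cc,
                        hw = hw, n = d[3])
  net$acts$se <- se_out

  dn <- fwd_cbr(net, se_out, "down_dw", training, depthwise = TRUE,
                stride = 2L)
  net$acts$down <- dn

  br <- list(fwd_cbr(net, dn, "aspp_pointwise", training))
  for (r in cfg$dilation_rates)
    br <- c(br, list(fwd_cbr(net, dn, sprintf("aspp_rate%d", r), training,
                             dilation = r)))
  Cb <- 32L
  d2 <- dim(dn)
  cat2 <- array(0, c(d2[1], d2[2], d2[3], Cb * length(br)))
  for (i in seq_along(br))
    cat2[, , , (i - 1L) * Cb + seq_len(Cb)] <- br[[i]]
  A <- fwd_cbr(net, cat2, "aspp_fuse", training)
  net$acts$aspp_fuse <- A

  dA <- dim(A); n2 <- dA[1] * dA[2]; N <- dA[3]
  M <- A; dim(M) <- c(n2 * N, C)
  if (cfg$pooling_mode == "learnable") {
    p <- net$params$lpool
    pre1p <- M %*% p$W1 + rep(p$b1, each = n2 * N)
    pre2p <- pre1p %*% p$W2 + p$b2
    Amap <- nn_sigmoid(drop(pre2p))
    Tm <- M * Amap
    dim(Tm) <- c(n2, N, C)
    pooled <- colSums(Tm)                           # (N, C)
    net$.cache$lpool <- list(M = M, pre1 = pre1p, Amap = Amap, n2 = n2,
                             N = N, dA = dA)
    net$acts$attention <- array(Amap, c(dA[1], dA[2], N))
  } else {
    Tm <- M; dim(Tm) <- c(n2, N, C)
    pooled <- colSums(Tm) / n2
    net$.cache$gap <- list(n2 = n2, N = N, dA = dA)
  }
  dim(pooled) <- c(N, C)
  drh <- nn_dropout(pooled, cfg$dropout_rate, training)
  net$.cache$head_drop <- drh$cache
  ph <- net$params$head
  z <- drop(drh$out %*% ph$W) + ph$b
  net$.cache$head <- list(x = drh$out, z = z)
  prob <- nn_sigmoid(z)
  net$.cache$prob <- prob
  prob
}

#' Reverse pass
#'
#' Propagates a gradient seeded at the classifier logit back through the
#' whole graph, filling `net$grads` (one entry per weight group) and
#' `net$stage_grads` (gradients at the spatial stages, used by Grad-CAM).
#' Must follow a [pneunet_forward()] call with `training = TRUE` for weight
#' gradients used in optimization, or `training = FALSE` for saliency.
#'
#' @param net The network (with a populated forward cache).
#' @param dz Gradient at the logit, one value per batch item.
#' @return The network, invisibly.
#' @export
pneunet_backward <- function(net, dz) {
  cfg <- net$config
  S <- cfg$stem_filters; C <- cfg$fusion_branches * S
  net$grads <- list()
  net$stage_grads <- list()
  cache <- net$.cache

  hc <- cache$head
  dz <- matrix(dz, ncol = 1)
  net$grads$head <- list(W = crossprod(hc$x, dz), b = sum(dz))
  dpool <- dz %*% t(matrix(net$params$head$W, ncol = 1))
  dpool <- nn_dropout_bwd(cache$head_drop, dpool)

  if (cfg$pooling_mode == "learnable") {
    lc <- cache$lpool
    n2 <- lc$n2; N <- lc$N
    dT <- array(rep(dpool, each = n2), c(n2 * N, C))   # (hw, n, c) order
    dM <- dT * lc$Amap
    dAmap <- rowSums(dT * lc$M)
    dpre2 <- dAmap * lc$Amap * (1 - lc$Amap)
    p <- net$params$lpool
    net$grads$lpool <- list(
      W2 = crossprod(lc$pre1, matrix(dpre2, ncol = 1)), b2 = sum(dpre2),
      W1 = NULL, b1 = NULL)
    dpre1 <- matrix(dpre2, ncol = 1) %*% t(matrix(p$W2, ncol = 1))
    net$grads$lpool$W1 <- crossprod(lc$M, dpre1)
    net$grads$lpool$b1 <- colSums(dpre1)
    dM <- dM + dpre1 %*% t(p$W1)
    dAct <- dM; dim(dAct) <- lc$dA
  } else {
    gc <- cache$gap
    n2 <- gc$n2; N <- gc$N
    dM <- array(rep(dpool / n2, each = n2), c(n2 * N, C))
    dAct <- dM; dim(dAct) <- gc$dA
  }
  net$stage_grads$aspp_fuse <- dAct

  dcat <- bwd_cbr(net, "aspp_fuse", dAct)
  Cb <- 32L
  ddn <- bwd_cbr(net, "aspp_pointwise", dcat[, , , seq_len(Cb), drop = FALSE])
  for (i in seq_along(cfg$dilation_rates)) {
    r <- cfg$dilation_rates[i]
    ddn <- ddn + bwd_cbr(net, sprintf("aspp_rate%d", r),
                         dcat[, , , i * Cb + seq_len(Cb), drop = FALSE])
  }
  net$stage_grads$down <- ddn

  dse <- bwd_cbr(net, "down_dw", ddn)
  net$stage_grads$se <- dse

  sc <- cache$se
  hw <- sc$hw; N <- sc$n
  dse_m <- dse; dim(dse_m) <- c(hw, N * C)
  dcc <- dse * rep(as.vector(sc$g), each = hw)
  dg <- matrix(colSums(dse_m * matrix(sc$cc, hw, N * C)), N, C)
  dpre2 <- dg * sc$g * (1 - sc$g)
  p <- net$params$se
  net$grads$se <- list(W2 = crossprod(sc$h1, dpre2), b2 = colSums(dpre2),
                       W1 = NULL, b1 = NULL)
  dh1 <- dpre2 %*% t(p$W2)
  dh1 <- dh1 * (sc$pre1 > 0)
  net$grads$se$W1 <- crossprod(sc$sq, dh1)
  net$grads$se$b1 <- colSums(dh1)
  dsq <- dh1 %*% t(p$W1)                             # (N, C)
  dcc <- dcc + array(rep(as.vector(dsq) / hw, each = hw), dim(dcc))
  net$stage_grads$concat <- dcc

  n_blocks <- cfg$fusion_branches - 1L
  dblock <- vector("list", n_blocks)
  ds0 <- dcc[, , , seq_len(S), drop = FALSE]
  for (i in seq_len(n_blocks))
    dblock[[i]] <- dcc[, , , i * S + seq_len(S), drop = FALSE]
  carry <- array(0, dim(ds0))
  for (i in rev(seq_len(n_blocks))) {
    dy <- dblock[[i]] + carry
    dy <- nn_dropout_bwd(cache[[sprintf("ds%d_drop", i)]], dy)
    dy <- bwd_cbr(net, sprintf("ds%d_pw", i), dy)
    carry <- bwd_cbr(net, sprintf("ds%d_dw", i), dy)
  }
  ds0 <- ds0 + carry
  net$stage_grads$stem <- ds0
  bwd_cbr(net, "stem", ds0)
  invisible(net)
}

#' Predict pneumonia probabilities
#'
#' @param net A built (typically trained) network.
#' @param X A 4-D batch `(H, W, N, C)`, a single feature map, or a list of
#'   feature maps as produced by [preprocess()].
#' @return Numeric vector of probabilities in (0, 1).
#' @export
pneunet_predict <- function(net, X) {
  if (is.list(X) && !is.array(X)) X <- stack_feature_maps(X)
  pneunet_forward(net, X, training = FALSE)
}

#' Stack feature maps into a batch tensor
#'
#' @param fms List of equally-shaped feature maps `(H, W, C)`.
#' @return A 4-D array `(H, W, N, C)`.
#' @export
stack_feature_maps <- function(fms) {
  d <- dim(fms[[1]])
  X <- array(0, c(d[1], d[2], length(fms), d[3]))
  for (i in seq_along(fms)) X[, , i, ] <- fms[[i]]
  X
}

#' Trainable-parameter count for one declared layer
#'
#' Standard parameter arithmetic: convolution `k^2*C_in*C_out + C_out`,
#' depthwise `k^2*C + C`, dense `in*out + out`, batch norm `2*C`, the
#' channel-attention block `(C*u + u) + (u*C + C)`, and the two-stage
#' learnable-pooling head `(C*h + h) + (h + 1)`.
#'
#' @param layer A list with a `kind` field (one of `"conv"`,
#'   `"depthwise_conv"`, `"dense"`, `"batch_norm"`, `"se_block"`,
#'   `"learnable_pool"`, `"concat"`, `"dropout"`, `"activation"`) plus the
#'   size fields that kind needs (`kernel`, `in_channels`, `out_channels`,
#'   `channels`, `units`, `squeeze_units`, `hidden_channels`, `bias`).
#' @return Nonnegative integer.
#' @examples
#' count_parameters(list(kind = "conv", kernel = 3, in_channels = 3,
#'                       out_channels = 32))             # 896
#' count_parameters(list(kind = "se_block", channels = 128,
#'                       squeeze_units = 8))             # 2184
#' @export
count_parameters <- function(layer) {
  kind <- layer$kind
  bias <- if (is.null(layer$bias)) TRUE else isTRUE(layer$bias)
  switch(kind,
    conv = layer$kernel^2 * layer$in_channels * layer$out_channels +
      if (bias) layer$out_channels else 0L,
    depthwise_conv = layer$kernel^2 * layer$channels +
      if (bias) layer$channels else 0L,
    dense = layer$in_channels * layer$out_channels +
      if (bias) layer$out_channels else 0L,
    batch_norm = 2L * layer$channels,
    se_block = {
      C <- layer$channels; u <- layer$squeeze_units
      (C * u + u) + (u * C + C)
    },
    learnable_pool = {
      C <- layer$in_channels
      h <- if (is.null(layer$hidden_channels)) C else layer$hidden_channels
      (C * h + h) + (h + 1L)
    },
    concat = 0L, dropout = 0L, activation = 0L,
    stopf("unknown layer kind '%s'", kind))
}

#' Per-layer parameter report
#'
#' One row per named weight group of the built network, counted from the
#' actual weight arrays, so the audit reflects the graph as constructed.
#'
#' @param net A built network.
#' @return A data frame (`layer`, `params`) of class `"param_report"` with
#'   a `total` attribute.
#' @export
param_report <- function(net) {
  rows <- vapply(net$params, function(g) sum(vapply(g, length, 1L)),
                 integer(1))
  out <- data.frame(layer = names(rows), params = unname(rows),
                    stringsAsFactors = FALSE)
  attr(out, "total") <- sum(rows)
  class(out) <- c("param_report", class(out))
  out
}

#' @export
print.param_report <- function(x, ...) {
  cat("Trainable parameters by layer\n")
  print.data.frame(x, row.names = FALSE)
  cat(sprintf("total: %d\n", attr(x, "total")))
  invisible(x)
}

#' Per-layer multiply-accumulate complexity report
#'
#' For every convolution stage: the dense-convolution cost per spatial
#' position (`k^2 * C_in * C_out`), and where the stage is depthwise-
#' separable also the factorized cost (`k^2 * C_in + C_in * C_out`).
#'
#' @param net A built network.
#' @return Data frame (`layer`, `standard_macs`, `separable_macs`).
#' @export
complexity_report <- function(net) {
  cfg <- net$config
  S <- cfg$stem_filters; C <- cfg$fusion_branches * S
  rows <- list(list("stem",
                    standard_conv_cost(conv_spec(3, cfg$input_channels, S)),
                    NA_real_))
  for (i in seq_len(cfg$fusion_branches - 1L))
    rows <- c(rows, list(list(sprintf("ds%d", i),
                              standard_conv_cost(conv_spec(3, S, S)),
                              separable_conv_cost(conv_spec(3, S, S)))))
  rows <- c(rows, list(list("down_dw",
                            standard_conv_cost(conv_spec(3, C, C)),
                            separable_conv_cost(conv_spec(3, C, C)))))
  rows <- c(rows, list(list("aspp_pointwise",
                            standard_conv_cost(conv_spec(1, C, 32)), NA_real_)))
  for (r in cfg$dilation_rates)
    rows <- c(rows, list(list(sprintf("aspp_rate%d", r),
                              standard_conv_cost(conv_spec(3, C, 32)),
                              NA_real_)))
  Ccat <- 32L * (1L + length(cfg$dilation_rates))
  rows <- c(rows, list(list("aspp_fuse",
                            standard_conv_cost(conv_spec(1, Ccat, C)),
                            NA_real_)))
  data.frame(layer = vapply(rows, `[[`, "", 1),
             standard_macs = vapply(rows, `[[`, 0, 2),
             separable_macs = vapply(rows, `[[`, 0, 3),
             stringsAsFactors = FALSE)
}

#' Stage output shapes
#'
#' Shape audit of the assembled graph: the spatial/channel shape after each
#' named stage for the configured input size.
#'
#' @param net A built network.
#' @return Named list of integer shape vectors.
#' @export
stage_shapes <- function(net) {
  cfg <- net$config
  H <- cfg$input_height; W <- cfg$input_width
  C <- cfg$fusion_branches * cfg$stem_filters
  H2 <- as.integer(ceiling(H / 2)); W2 <- as.integer(ceiling(W / 2))
  list(input = c(H, W, cfg$input_channels),
       stem = c(H, W, cfg$stem_filters),
       concat = c(H, W, C),
       se = c(H, W, C),
       down = c(H2, W2, C),
       aspp_fuse = c(H2, W2, C),
       pooled = C,
       output = 1L)
}
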