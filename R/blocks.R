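# The four bespoke building blocks of the network, exposed as pure numeric
# operations on single feature maps. Each takes an explicit weight list so it
# can be tested independently of any trained model; the assembled network in
# model.R calls the same engine on batched tensors.

#' Construct a feature map
#'
#' A feature map is a rank-3 numeric array indexed (row, column, channel) —
#' the tensor flowing between network blocks.
#'
#' @param values Numeric array with `dim` of length 3 (`H x W x C`), or a
#'   matrix (taken as a single-channel map). All values must be finite.
#' @return The validated array with class `"feature_map"`.
#' @examples
#' fm <- feature_map(array(rnorm(2 * 3 * 4), c(2, 3, 4)))
#' dim(fm)
#' @export
feature_map <- function(values) {
  if (is.matrix(values)) dim(values) <- c(dim(values), 1L)
  if (!is.array(values) || length(dim(values)) != 3)
    stopf("a feature map must be a 3-D array (height x width x channels)")
  if (any(dim(values) < 1)) stopf("feature map dimensions must be >= 1")
  if (!all(is.finite(values))) stopf("feature map values must be finite")
  structure(values, class = c("feature_map", class(values)))
}

as_feature_map <- function(x) {
  if (inherits(x, "feature_map")) x else feature_map(x)
}

#' Describe one convolution layer
#'
#' Declarative description of a convolution used both for cost accounting
#' and parameter auditing.
#'
#' @param kernel Kernel size `k` (square kernels).
#' @param in_channels,out_channels Channel counts. A depthwise convolution
#'   must have `out_channels == in_channels`.
#' @param stride,dilation Positive integers.
#' @param bias Whether the layer carries a bias term.
#' @param depthwise Whether the convolution is depthwise (one spatial filter
#'   per channel, no channel mixing).
#' @param padding `"same"` (spatial dims preserved at stride 1) or `"valid"`.
#' @return A list with class `"conv_spec"`.
#' @export
conv_spec <- function(kernel, in_channels, out_channels, stride = 1L,
                      dilation = 1L, bias = TRUE, depthwise = FALSE,
                      padding = c("same", "valid")) {
  padding <- match.arg(padding)
  for (v in list(kernel, in_channels, out_channels, stride, dilation))
    if (!is_count(v)) stopf("conv_spec fields must be positive integers")
  if (depthwise && out_channels != in_channels)
    stopf("a depthwise convolution requires out_channels == in_channels")
  structure(list(kernel = as.integer(kernel),
                 in_channels = as.integer(in_channels),
                 out_channels = as.integer(out_channels),
                 stride = as.integer(stride), dilation = as.integer(dilation),
                 bias = isTRUE(bias), depthwise = isTRUE(depthwise),
                 padding = padding),
            class = "conv_spec")
}

#' Multiply-accumulate cost of a standard convolution
#'
#' Cost per spatial position of a dense convolution: `k^2 * C_in * C_out`.
#'
#' @param spec A [conv_spec()] with `depthwise = FALSE`.
#' @return Nonnegative count of multiply-accumulates per output position.
#' @seealso [separable_conv_cost()]
#' @examples
#' standard_conv_cost(conv_spec(3, 3, 32))   # 864
#' @export
standard_conv_cost <- function(spec) {
  stopifnot(inherits(spec, "conv_spec"))
  if (spec$depthwise)
    stopf("standard_conv_cost is defined for dense convolutions only")
  spec$kernel^2 * spec$in_channels * spec$out_channels
}

#' Multiply-accumulate cost of a depthwise-separable convolution
#'
#' Cost per spatial position after factorizing into a depthwise spatial
#' filter plus a pointwise channel mixer: `k^2 * C_in + C_in * C_out`. The
#' ratio to [standard_conv_cost()] is `1/C_out + 1/k^2`.
#'
#' @param spec A [conv_spec()].
#' @return Nonnegative count of multiply-accumulates per output position.
#' @examples
#' separable_conv_cost(conv_spec(3, 128, 32)) # 5248
#' @export
separable_conv_cost <- function(spec) {
  stopifnot(inherits(spec, "conv_spec"))
  spec$kernel^2 * spec$in_channels + spec$in_channels * spec$out_channels
}

#' One-dimensional atrous (dilated) convolution
#'
#' Valid-mode dilated convolution `y[i] = sum_k x[i + r*k] * w[k]` — the
#' reference oracle for the 2-D dilated convolutions inside the pyramid
#' pooling module.
#'
#' @param signal Numeric vector `x`.
#' @param weights Numeric kernel `w`.
#' @param rate Dilation rate `r` (spacing between kernel taps).
#' @return Numeric vector of length `length(signal) - (length(weights)-1)*rate`.
#' @examples
#' atrous_conv_1d(1:5, c(1, 1, 1), rate = 2)  # 1+3+5 = 9
#' @export
atrous_conv_1d <- function(signal, weights, rate = 1L) {
  if (!is_count(rate)) stopf("rate must be a positive integer")
  n <- length(signal); m <- length(weights)
  span <- (m - 1L) * rate + 1L
  if (n < span)
    stopf("signal of length %d is shorter than the kernel span %d ((%d-1)*%d + 1)",
          n, span, m, rate)
  n_out <- n - (m - 1L) * rate
  taps <- vapply(seq_len(m), function(k) {
    signal[seq_len(n_out) + (k - 1L) * rate] * weights[k]
  }, numeric(n_out))
  if (n_out == 1L) sum(taps) else rowSums(matrix(taps, n_out, m))
}

#' Squeeze: per-channel global spatial mean
#'
#' The squeeze step of the squeeze-and-excitation block:
#' `s_c = mean over (i, j) of x[i, j, c]`.
#'
#' @param fm A [feature_map()].
#' @return Numeric vector of length `channels`.
#' @export
se_squeeze <- function(fm) {
  fm <- as_feature_map(fm)
  d <- dim(fm)
  colMeans(matrix(fm, d[1] * d[2], d[3]))
}

#' Squeeze-and-excitation configuration
#'
#' @param channels Number of channels gated (network default 128).
#' @param squeeze_units Bottleneck width (default 8); must be `< channels`.
#' @export
se_config <- function(channels = 128L, squeeze_units = 8L) {
  if (!is_count(channels) || !is_count(squeeze_units))
    stopf("channels and squeeze_units must be positive integers")
  if (squeeze_units >= channels)
    stopf("squeeze_units must be smaller than channels")
  structure(list(channels = as.integer(channels),
                 squeeze_units = as.integer(squeeze_units)),
            class = "se_config")
}

#' Random or zero-initialized weights for a squeeze-and-excitation block
#'
#' @param cfg An [se_config()].
#' @param init `"zeros"` or `"random"` (variance-scaling fan-in).
#' @param seed Optional seed for random init.
#' @return List with dense kernels `W1` (`C x u`), `W2` (`u x C`) and biases
#'   `b1`, `b2`.
#' @export
se_weights <- function(cfg, init = c("zeros", "random"), seed = NULL) {
  init <- match.arg(init)
  C <- cfg$channels; u <- cfg$squeeze_units
  if (init == "zeros")
    return(list(W1 = matrix(0, C, u), b1 = numeric(u),
                W2 = matrix(0, u, C), b2 = numeric(C)))
  draw <- function() list(W1 = matrix(stats::rnorm(C * u, sd = sqrt(2 / C)), C, u),
                          b1 = numeric(u),
                          W2 = matrix(stats::rnorm(u * C, sd = sqrt(2 / u)), u, C),
                          b2 = numeric(C))
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Squeeze-and-excitation channel attention
#'
#' Pools each channel to a scalar (squeeze), passes the vector through a
#' two-layer bottleneck (rectifier after the squeeze layer), applies a
#' sigmoid to obtain per-channel gates in (0, 1), and rescales every channel
#' of the input by its gate. Spatial dimensions are unchanged.
#'
#' @param fm A [feature_map()] with `channels == cfg$channels`.
#' @param cfg An [se_config()].
#' @param weights A list as produced by [se_weights()].
#' @return The gated feature map, with the gate vector attached as attribute
#'   `"gates"`.
#' @export
se_block <- function(fm, cfg, weights) {
  fm <- as_feature_map(fm)
  d <- dim(fm)
  if (d[3] != cfg$channels)
    stopf("feature map has %d channels but the block expects %d",
          d[3], cfg$channels)
  s <- se_squeeze(fm)
  h <- pmax(drop(s %*% weights$W1) + weights$b1, 0)
  g <- nn_sigmoid(drop(h %*% weights$W2) + weights$b2)
  out <- fm * rep(g, each = d[1] * d[2])
  structure(feature_map(array(out, d)), gates = g)
}

#' Atrous spatial pyramid pooling configuration
#'
#' @param in_channels Input channels (default 128).
#' @param branch_channels Channels per parallel branch (default 32).
#' @param dilation_rates Strictly increasing dilation rates for the 3x3
#'   branches (default `c(1, 3, 6)`); a 1x1 branch is always present, so the
#'   fuse convolution sees `branch_channels * (1 + length(dilation_rates))`
#'   channels.
#' @param fuse_channels Output channels of the 1x1 fuse convolution.
#' @export
aspp_config <- function(in_channels = 128L, branch_channels = 32L,
                        dilation_rates = c(1L, 3L, 6L),
                        fuse_channels = 128L) {
  if (any(diff(dilation_rates) <= 0) || any(dilation_rates < 1))
    stopf("dilation_rates must be strictly increasing positive integers")
  structure(list(in_channels = as.integer(in_channels),
                 branch_channels = as.integer(branch_channels),
                 dilation_rates = as.integer(dilation_rates),
                 fuse_channels = as.integer(fuse_channels)),
            class = "aspp_config")
}

#' Random or zero-initialized weights for the pyramid pooling module
#'
#' @param cfg An [aspp_config()].
#' @param init `"zeros"` or `"random"`.
#' @param seed Optional seed.
#' @return List with `pointwise` (1x1 branch), one entry per dilated branch
#'   (`rate1`, `rate3`, ...), and `fuse`; each holds a kernel array
#'   `(k, k, C_in, C_out)` and a bias.
#' @export
aspp_weights <- function(cfg, init = c("zeros", "random"), seed = NULL) {
  init <- match.arg(init)
  Cin <- cfg$in_channels; Cb <- cfg$branch_channels
  Cf <- cfg$fuse_channels
  Ccat <- Cb * (1L + length(cfg$dilation_rates))
  mk <- function(k, ci, co) {
    W <- if (init == "zeros") array(0, c(k, k, ci, co))
    else array(stats::rnorm(k * k * ci * co, sd = sqrt(2 / (k * k * ci))),
               c(k, k, ci, co))
    list(W = W, b = numeric(co))
  }
  build <- function() {
    w <- list(pointwise = mk(1L, Cin, Cb))
    for (r in cfg$dilation_rates) w[[paste0("rate", r)]] <- mk(3L, Cin, Cb)
    w$fuse <- mk(1L, Ccat, Cf)
    w
  }
  if (is.null(seed) || init == "zeros") build() else with_seed(seed, build())
}

#' Atrous spatial pyramid pooling
#'
#' Four parallel branches — a 1x1 convolution and 3x3 dilated convolutions
#' at the configured rates, all same-padded so spatial dims are preserved —
#' concatenated along channels and fused by a 1x1 convolution.
#'
#' @param fm A [feature_map()] with `channels == cfg$in_channels`.
#' @param cfg An [aspp_config()].
#' @param weights A list as produced by [aspp_weights()].
#' @return Feature map of shape `H x W x fuse_channels`.
#' @export
aspp <- function(fm, cfg, weights) {
  fm <- as_feature_map(fm)
  d <- dim(fm)
  if (d[3] != cfg$in_channels)
    stopf("feature map has %d channels but the module expects %d",
          d[3], cfg$in_channels)
  X <- fm; dim(X) <- c(d[1], d[2], 1L, d[3])
  branches <- list(nn_conv2d(X, weights$pointwise$W, weights$pointwise$b)$out)
  for (r in cfg$dilation_rates) {
    w <- weights[[paste0("rate", r)]]
    branches <- c(branches, list(nn_conv2d(X, w$W, w$b, dilation = r)$out))
  }
  Cb <- cfg$branch_channels
  cat_ <- array(0, c(d[1], d[2], 1L, Cb * length(branches)))
  for (i in seq_along(branches))
    cat_[, , , (i - 1L) * Cb + seq_len(Cb)] <- branches[[i]]
  fused <- nn_conv2d(cat_, weights$fuse$W, weights$fuse$b)$out
  feature_map(array(fused, c(d[1], d[2], cfg$fuse_channels)))
}

#' Learnable pooling configuration
#'
#' @param in_channels Channels of the pooled map (default 128).
#' @param hidden_channels Width of the first 1x1 convolution of the
#'   attention head (default 128).
#' @export
learnable_pooling_config <- function(in_channels = 128L,
                                     hidden_channels = 128L) {
  structure(list(in_channels = as.integer(in_channels),
                 hidden_channels = as.integer(hidden_channels)),
            class = "learnable_pooling_config")
}

#' Random or zero-initialized weights for the learnable pooling head
#'
#' Two-stage attention head: 1x1 convolution `in -> hidden` with bias
#' followed by 1x1 convolution `hidden -> 1` with bias (16,512 + 129 =
#' 16,641 parameters at the 128/128 default), then a sigmoid.
#'
#' @param cfg A [learnable_pooling_config()].
#' @param init `"zeros"` or `"random"`.
#' @param seed Optional seed.
#' @export
learnable_pooling_weights <- function(cfg, init = c("zeros", "random"),
                                      seed = NULL) {
  init <- match.arg(init)
  Ci <- cfg$in_channels; Ch <- cfg$hidden_channels
  build <- function() {
    if (init == "zeros")
      list(W1 = matrix(0, Ci, Ch), b1 = numeric(Ch),
           W2 = matrix(0, Ch, 1), b2 = 0)
    else
      list(W1 = matrix(stats::rnorm(Ci * Ch, sd = sqrt(2 / Ci)), Ci, Ch),
           b1 = numeric(Ch),
           W2 = matrix(stats::rnorm(Ch, sd = sqrt(2 / Ch)), Ch, 1),
           b2 = 0)
  }
  if (is.null(seed) || init == "zeros") build() else with_seed(seed, build())
}

#' Trainable spatial-attention pooling
#'
#' Computes a sigmoid spatial attention map `A` in `(0,1)^(H x W)` from two
#' stacked 1x1 convolutions and returns the unnormalized weighted sum
#' `F_pooled[c] = sum_(i,j) fm[i, j, c] * A[i, j]` — the trainable
#' replacement for global average pooling. No division by `sum(A)` is
#' applied (a normalized variant is available via `normalize = TRUE`).
#'
#' @param fm A [feature_map()] with `channels == cfg$in_channels`.
#' @param cfg A [learnable_pooling_config()].
#' @param weights A list as produced by [learnable_pooling_weights()].
#' @param normalize If `TRUE`, divide the pooled vector by `sum(A)`.
#' @return Numeric vector of length `in_channels` with the attention map
#'   attached as attribute `"attention"` (an `H x W` matrix).
#' @export
learnable_pool <- function(fm, cfg, weights, normalize = FALSE) {
  fm <- as_feature_map(fm)
  d <- dim(fm)
  if (d[3] != cfg$in_channels)
    stopf("feature map has %d channels but the pooling head expects %d",
          d[3], cfg$in_channels)
  n <- d[1] * d[2]
  M <- matrix(fm, n, d[3])
  pre <- (M %*% weights$W1 + rep(weights$b1, each = n)) %*% weights$W2 +
    weights$b2
  A <- nn_sigmoid(drop(pre))
  pooled <- colSums(M * A)
  if (normalize) pooled <- pooled / sum(A)
  structure(pooled, attention = matrix(A, d[1], d[2]))
}

#' Global average pooling
#'
#' Per-channel spatial mean — the fixed pooling that [learnable_pool()]
#' replaces; identical in formula to [se_squeeze()]. Used when the network
#' is built with `pooling_mode = "gap"`.
#'
#' @param fm A [feature_map()].
#' @return Numeric vector of length `channels`.
#' @export
gap_pool <- function(fm) se_squeeze(fm)
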