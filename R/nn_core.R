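# Numeric engine for the network: 2-D convolutions, batch normalization,
# activations and dropout, with hand-derived reverse-mode gradients.
#
# Batched activations are stored as 4-D arrays with dims (H, W, N, C): with
# R's column-major layout, reshaping a (H, W, N, C) block to a (H*W*N, C)
# matrix is free, so every convolution reduces to one BLAS matrix product
# per kernel tap. All functions here are internal; the public block API in
# blocks.R wraps them for single feature maps.

# "same"-padding arithmetic: output = ceiling(n / stride); asymmetric pad
# (extra pixel trailing) for even inputs under stride 2.
pad_amounts <- function(n, k, stride = 1L, dilation = 1L) {
  keff <- (k - 1L) * dilation + 1L
  out <- as.integer(ceiling(n / stride))
  pad <- max((out - 1L) * stride + keff - n, 0L)
  list(beg = pad %/% 2L, end = pad - pad %/% 2L, out = out)
}

nn_pad <- function(X, ph, pw) {
  if (ph$beg + ph$end + pw$beg + pw$end == 0L) return(X)
  d <- dim(X)
  Xp <- array(0, c(d[1] + ph$beg + ph$end, d[2] + pw$beg + pw$end, d[3], d[4]))
  Xp[ph$beg + seq_len(d[1]), pw$beg + seq_len(d[2]), , ] <- X
  Xp
}

# Standard convolution, weights (k, k, C_in, C_out), bias length C_out.
nn_conv2d <- function(X, W, b, stride = 1L, dilation = 1L) {
  d <- dim(X); H <- d[1]; Wd <- d[2]; N <- d[3]; C <- d[4]
  k <- dim(W)[1]; Cout <- dim(W)[4]
  if (k == 1L && stride == 1L) {
    M <- X; dim(M) <- c(H * Wd * N, C)
    Y <- M %*% matrix(W, C, Cout)
    Y <- Y + rep(b, each = nrow(Y))
    dim(Y) <- c(H, Wd, N, Cout)
    return(list(out = Y, cache = list(
      X = X, W = W, k = 1L, stride = 1L, dilation = 1L, dimX = d)))
  }
  ph <- pad_amounts(H, k, stride, dilation)
  pw <- pad_amounts(Wd, k, stride, dilation)
  Xp <- nn_pad(X, ph, pw)
  Ho <- ph$out; Wo <- pw$out
  Y <- matrix(rep(b, each = Ho * Wo * N), Ho * Wo * N, Cout)
  for (a in seq_len(k)) for (bb in seq_len(k)) {
    ri <- (a - 1L) * dilation + seq(1L, by = stride, length.out = Ho)
    ci <- (bb - 1L) * dilation + seq(1L, by = stride, length.out = Wo)
    M <- Xp[ri, ci, , , drop = FALSE]
    dim(M) <- c(Ho * Wo * N, C)
    Y <- Y + M %*% matrix(W[a, bb, , ], C, Cout)
  }
  dim(Y) <- c(Ho, Wo, N, Cout)
  list(out = Y, cache = list(
    Xp = Xp, W = W, k = k, stride = stride, dilation = dilation,
    dimX = d, ph = ph, pw = pw))
}

nn_conv2d_bwd <- function(cache, dY) {
  k <- cache$k; W <- cache$W
  C <- dim(W)[3]; Cout <- dim(W)[4]
  dOut <- dim(dY); Ho <- dOut[1]; Wo <- dOut[2]; N <- dOut[3]
  dYm <- dY; dim(dYm) <- c(Ho * Wo * N, Cout)
  db <- colSums(dYm)
  if (k == 1L && cache$stride == 1L) {
    M <- cache$X; dim(M) <- c(Ho * Wo * N, C)
    dW <- crossprod(M, dYm)
    dX <- dYm %*% t(matrix(W, C, Cout))
    dim(dW) <- dim(W)
    dim(dX) <- cache$dimX
    return(list(dX = dX, dW = dW, db = db))
  }
  Xp <- cache$Xp; s <- cache$stride; dl <- cache$dilation
  dXp <- array(0, dim(Xp))
  dW <- array(0, dim(W))
  for (a in seq_len(k)) for (bb in seq_len(k)) {
    ri <- (a - 1L) * dl + seq(1L, by = s, length.out = Ho)
    ci <- (bb - 1L) * dl + seq(1L, by = s, length.out = Wo)
    M <- Xp[ri, ci, , , drop = FALSE]
    dim(M) <- c(Ho * Wo * N, C)
    dW[a, bb, , ] <- crossprod(M, dYm)
    dM <- dYm %*% t(matrix(W[a, bb, , ], C, Cout))
    dim(dM) <- c(Ho, Wo, N, C)
    dXp[ri, ci, , ] <- dXp[ri, ci, , , drop = FALSE] + dM
  }
  d <- cache$dimX
  dX <- dXp[cache$ph$beg + seq_len(d[1]), cache$pw$beg + seq_len(d[2]), , ,
            drop = FALSE]
  dim(dX) <- d
  list(dX = dX, dW = dW, db = db)
}

# Depthwise convolution, weights (k, k, C), bias length C.
nn_dwconv2d <- function(X, W, b, stride = 1L, dilation = 1L) {
  d <- dim(X); H <- d[1]; Wd <- d[2]; N <- d[3]; C <- d[4]
  k <- dim(W)[1]
  ph <- pad_amounts(H, k, stride, dilation)
  pw <- pad_amounts(Wd, k, stride, dilation)
  Xp <- nn_pad(X, ph, pw)
  Ho <- ph$out; Wo <- pw$out
  n_pos <- Ho * Wo * N
  Y <- matrix(rep(b, each = n_pos), n_pos, C)
  for (a in seq_len(k)) for (bb in seq_len(k)) {
    ri <- (a - 1L) * dilation + seq(1L, by = stride, length.out = Ho)
    ci <- (bb - 1L) * dilation + seq(1L, by = stride, length.out = Wo)
    M <- Xp[ri, ci, , , drop = FALSE]
    dim(M) <- c(n_pos, C)
    Y <- Y + M * rep(W[a, bb, ], each = n_pos)
  }
  dim(Y) <- c(Ho, Wo, N, C)
  list(out = Y, cache = list(
    Xp = Xp, W = W, k = k, stride = stride, dilation = dilation,
    dimX = d, ph = ph, pw = pw))
}

nn_dwconv2d_bwd <- function(cache, dY) {
  k <- cache$k; W <- cache$W
  dOut <- dim(dY); Ho <- dOut[1]; Wo <- dOut[2]; N <- dOut[3]; C <- dOut[4]
  n_pos <- Ho * Wo * N
  dYm <- dY; dim(dYm) <- c(n_pos, C)
  db <- colSums(dYm)
  Xp <- cache$Xp; s <- cache$stride; dl <- cache$dilation
  dXp <- array(0, dim(Xp))
  dW <- array(0, dim(W))
  for (a in seq_len(k)) for (bb in seq_len(k)) {
    ri <- (a - 1L) * dl + seq(1L, by = s, length.out = Ho)
    ci <- (bb - 1L) * dl + seq(1L, by = s, length.out = Wo)
    M <- Xp[ri, ci, , , drop = FALSE]
    dim(M) <- c(n_pos, C)
    dW[a, bb, ] <- colSums(M * dYm)
    dM <- dYm * rep(W[a, bb, ], each = n_pos)
    dim(dM) <- c(Ho, Wo, N, C)
    dXp[ri, ci, , ] <- dXp[ri, ci, , , drop = FALSE] + dM
  }
  d <- cache$dimX
  dX <- dXp[cache$ph$beg + seq_len(d[1]), cache$pw$beg + seq_len(d[2]), , ,
            drop = FALSE]
  dim(dX) <- d
  list(dX = dX, dW = dW, db = db)
}

# Channel-wise batch normalization over the (H, W, N) axes.
nn_batchnorm <- function(X, gamma, beta, state, training,
                         momentum = 0.9, eps = 1e-5) {
  d <- dim(X); n <- d[1] * d[2] * d[3]; C <- d[4]
  M <- X; dim(M) <- c(n, C)
  if (training) {
    mu <- colMeans(M)
    Mc <- M - rep(mu, each = n)
    v <- colSums(Mc * Mc) / n
    state$mean <- momentum * state$mean + (1 - momentum) * mu
    state$var <- momentum * state$var + (1 - momentum) * v
  } else {
    mu <- state$mean
    v <- state$var
    Mc <- M - rep(mu, each = n)
  }
  invstd <- 1 / sqrt(v + eps)
  xhat <- Mc * rep(invstd, each = n)
  Y <- xhat * rep(gamma, each = n) + rep(beta, each = n)
  dim(Y) <- d
  list(out = Y,
       cache = list(xhat = xhat, invstd = invstd, gamma = gamma,
                    d = d, training = training, mu = mu, v = v),
       state = state)
}

nn_batchnorm_bwd <- function(cache, dY) {
  d <- cache$d; n <- d[1] * d[2] * d[3]; C <- d[4]
  dYm <- dY; dim(dYm) <- c(n, C)
  xhat <- cache$xhat
  dgamma <- colSums(dYm * xhat)
  dbeta <- colSums(dYm)
  g_inv <- cache$gamma * cache$invstd
  if (cache$training) {
    dX <- (dYm - rep(dbeta / n, each = n) -
             xhat * rep(dgamma / n, each = n)) * rep(g_inv, each = n)
  } else {
    dX <- dYm * rep(g_inv, each = n)  # running stats are constants
  }
  dim(dX) <- d
  list(dX = dX, dgamma = dgamma, dbeta = dbeta)
}

nn_relu <- function(X) {
  mask <- X > 0
  list(out = X * mask, cache = mask)
}
nn_relu_bwd <- function(cache, dY) dY * cache

nn_sigmoid <- function(X) 1 / (1 + exp(-X))

# Inverted dropout: scaling at train time so eval is the identity.
nn_dropout <- function(X, rate, training) {
  if (!training || rate <= 0) return(list(out = X, cache = NULL))
  keep <- 1 - rate
  mask <- array(stats::rbinom(length(X), 1L, keep), dim(X)) / keep
  list(out = X * mask, cache = mask)
}
nn_dropout_bwd <- function(cache, dY) if (is.null(cache)) dY else dY * cache
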