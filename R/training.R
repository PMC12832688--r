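# Optimization recipe: Adam on binary cross-entropy with L2 weight decay on
# kernels, dropout, early stopping on validation loss with best-checkpoint
# selection, and a complete per-epoch history.

#' Training configuration
#'
#' Defaults are the published recipe: Adam with beta1 = 0.9, beta2 = 0.999,
#' fixed learning rate 0.001, batch size 32, up to 50 epochs, early-stopping
#' patience 7, L2 weight decay lambda = 0.001 on convolution/dense kernels
#' (not biases or batch-norm parameters), dropout rate 0.3.
#'
#' @param learning_rate,beta1,beta2 Adam hyperparameters.
#' @param batch_size Minibatch size.
#' @param max_epochs Maximum epochs.
#' @param patience Early-stopping patience (epochs without a strict
#'   validation-loss improvement).
#' @param l2_lambda Weight-decay coefficient.
#' @param dropout_rate Dropout rate (also recorded in the architecture).
#' @param seed Seed for shuffling and dropout masks.
#' @return A list of class `"train_config"`.
#' @export
train_config <- function(learning_rate = 0.001, beta1 = 0.9, beta2 = 0.999,
                         batch_size = 32L, max_epochs = 50L, patience = 7L,
                         l2_lambda = 0.001, dropout_rate = 0.3, seed = 42L) {
  if (!is_count(patience)) stopf("patience must be a positive integer")
  if (learning_rate < 0 || beta1 < 0 || beta1 >= 1 || beta2 < 0 || beta2 >= 1)
    stopf("optimizer rates out of range")
  structure(list(learning_rate = learning_rate, beta1 = beta1, beta2 = beta2,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 l2_lambda = l2_lambda, dropout_rate = dropout_rate,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Binary cross-entropy
#'
#' Mean of `-(y log p + (1-y) log(1-p))` with probabilities clamped to
#' `[eps, 1-eps]`, `eps = 1e-7`. The L2 penalty is added separately (see
#' [l2_penalty()]).
#'
#' @param p Predicted probabilities.
#' @param y Binary labels (0/1).
#' @return Nonnegative scalar.
#' @examples
#' bce_loss(0.5, 1)  # log(2)
#' @export
bce_loss <- function(p, y) {
  eps <- 1e-7
  p <- clamp(p, eps, 1 - eps)
  mean(-(y * log(p) + (1 - y) * log(1 - p)))
}

#' L2 kernel penalty
#'
#' `lambda * sum(W^2)` over convolution and dense kernels only; biases and
#' batch-norm parameters are excluded. Zero iff every kernel is zero.
#'
#' @param net A built network.
#' @param lambda Weight-decay coefficient.
#' @return Nonnegative scalar.
#' @export
l2_penalty <- function(net, lambda) {
  if (lambda == 0) return(0)
  s <- 0
  for (ke in kernel_elements(net$params))
    s <- s + sum(net$params[[ke[1]]][[ke[2]]]^2)
  lambda * s
}

#' Early-stopping bookkeeping over a validation-loss trace
#'
#' `best_epoch` is the earliest epoch attaining the minimum loss seen before
#' stopping; training stops after `patience` consecutive epochs without a
#' strict improvement over the running best, so `stopped_epoch` equals
#' `best_epoch + patience` when the trigger fires (and the trace length
#' otherwise).
#'
#' @param val_losses Numeric vector, one loss per epoch.
#' @param patience Positive integer.
#' @return List with `stopped_epoch` and `best_epoch`.
#' @examples
#' early_stopping_trace(c(0.5, rep(0.6, 7)), patience = 7)  # stop 8, best 1
#' @export
early_stopping_trace <- function(val_losses, patience) {
  if (length(val_losses) == 0) stopf("empty validation-loss trace")
  if (!is_count(patience)) stopf("patience must be a positive integer")
  best <- Inf; best_epoch <- 0L; wait <- 0L
  for (e in seq_along(val_losses)) {
    if (val_losses[e] < best) {
      best <- val_losses[e]; best_epoch <- e; wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= patience)
        return(list(stopped_epoch = e, best_epoch = best_epoch))
    }
  }
  list(stopped_epoch = length(val_losses), best_epoch = best_epoch)
}

adam_init <- function(params) {
  st <- list(t = 0L, m = list(), v = list())
  for (g in names(params)) for (el in names(params[[g]])) {
    key <- paste0(g, ".", el)
    st$m[[key]] <- array(0, dim(as.array(params[[g]][[el]])))
    st$v[[key]] <- st$m[[key]]
  }
  st
}

adam_step <- function(net, st, cfg) {
  st$t <- st$t + 1L
  kset <- vapply(kernel_elements(net$params),
                 function(ke) paste0(ke[1], ".", ke[2]), "")
  bc1 <- 1 - cfg$beta1^st$t
  bc2 <- 1 - cfg$beta2^st$t
  for (g in names(net$params)) for (el in names(net$params[[g]])) {
    grad <- net$grads[[g]][[el]]
    if (is.null(grad)) next
    key <- paste0(g, ".", el)
    if (cfg$l2_lambda > 0 && key %in% kset)
      grad <- grad + 2 * cfg$l2_lambda * net$params[[g]][[el]]
    st$m[[key]] <- cfg$beta1 * st$m[[key]] + (1 - cfg$beta1) * grad
    st$v[[key]] <- cfg$beta2 * st$v[[key]] + (1 - cfg$beta2) * grad^2
    upd <- cfg$learning_rate * (st$m[[key]] / bc1) /
      (sqrt(st$v[[key]] / bc2) + 1e-8)
    # strip dims so the parameter keeps its original structure
    net$params[[g]][[el]] <- net$params[[g]][[el]] - as.vector(upd)
  }
  st
}

evaluate_split <- function(net, X, y, batch_size = 64L) {
  N <- dim(X)[3]
  probs <- numeric(N)
  for (start in seq(1L, N, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, N)
    probs[idx] <- pneunet_forward(net, X[, , idx, , drop = FALSE],
                                  training = FALSE)
  }
  list(loss = bce_loss(probs, y), acc = mean((probs >= 0.5) == (y == 1)),
       probs = probs)
}

#' Train the network
#'
#' Adam updates on minibatch binary cross-entropy plus the L2 kernel
#' penalty; dropout active only during training; a checkpoint is captured at
#' every new validation-loss minimum; training halts early after
#' `cfg$patience` epochs without improvement. Shuffling and dropout are
#' seeded by `cfg$seed`, so identical configurations reproduce identical
#' histories (single-threaded).
#'
#' @param net A network from [build_pneunet()].
#' @param data List with `train` and `val`, each a list `x` (4-D batch
#'   tensor `(H, W, N, C)`) and `y` (0/1 labels, 1 = pneumonia).
#' @param cfg A [train_config()].
#' @param verbose Print one line per epoch.
#' @return List with `checkpoint` (best weights, a `"pneunet_checkpoint"`)
#'   and `history` (data frame: epoch, train_loss, train_acc, val_loss,
#'   val_acc; attributes `best_epoch`, `stopped_epoch`).
#' @export
train_pneunet <- function(net, data, cfg = train_config(), verbose = FALSE) {
  Xtr <- data$train$x; ytr <- data$train$y
  Xva <- data$val$x; yva <- data$val$y
  Ntr <- dim(Xtr)[3]
  if (is.null(Ntr) || Ntr == 0) stopf("empty training set")
  if (length(intersect(attr(Xtr, "ids"), attr(Xva, "ids"))) > 0)
    stopf("train and validation sets overlap")
  hist <- data.frame(epoch = integer(), train_loss = double(),
                     train_acc = double(), val_loss = double(),
                     val_acc = double())
  best_loss <- Inf; best_epoch <- 0L; wait <- 0L
  best_ckpt <- NULL
  st <- adam_init(net$params)
  with_seed(cfg$seed, {
    for (epoch in seq_len(cfg$max_epochs)) {
      ord <- sample.int(Ntr)
      batch_losses <- c(); batch_accs <- c()
      for (start in seq(1L, Ntr, by = cfg$batch_size)) {
        idx <- ord[start:min(start + cfg$batch_size - 1L, Ntr)]
        xb <- Xtr[, , idx, , drop = FALSE]
        yb <- ytr[idx]
        p <- pneunet_forward(net, xb, training = TRUE)
        loss <- bce_loss(p, yb) + l2_penalty(net, cfg$l2_lambda)
        if (!is.finite(loss))
          stopf("non-finite training loss at epoch %d; aborting", epoch)
        batch_losses <- c(batch_losses, loss)
        batch_accs <- c(batch_accs, mean((p >= 0.5) == (yb == 1)))
        pneunet_backward(net, (p - yb) / length(yb))
        st <- adam_step(net, st, cfg)
      }
      # exact inference statistics for this epoch's weights (precise BN)
      refresh_bn_stats(net, Xtr)
      ev <- evaluate_split(net, Xva, yva)
      hist[epoch, ] <- list(epoch, mean(batch_losses), mean(batch_accs),
                            ev$loss, ev$acc)
      if (verbose)
        message(sprintf(
          "epoch %02d  train_loss %.4f acc %.3f | val_loss %.4f acc %.3f",
          epoch, mean(batch_losses), mean(batch_accs), ev$loss, ev$acc))
      if (ev$loss < best_loss) {
        best_loss <- ev$loss; best_epoch <- epoch; wait <- 0L
        best_ckpt <- pneunet_checkpoint(net, best_epoch = epoch,
                                        val_loss_at_best = ev$loss)
      } else {
        wait <- wait + 1L
        if (wait >= cfg$patience) break
      }
    }
  })
  if (is.null(best_ckpt))
    best_ckpt <- pneunet_checkpoint(net, best_epoch = nrow(hist),
                                    val_loss_at_best = hist$val_loss[nrow(hist)])
  attr(hist, "best_epoch") <- best_ckpt$best_epoch
  attr(hist, "stopped_epoch") <- nrow(hist)
  list(checkpoint = best_ckpt, history = hist)
}
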