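# Tiny nets (8x8 inputs, batches of a few images) keep these unit tests in
# the seconds range; the full desk-scale run lives in the acceptance suite.

tiny_data <- function(n = 8, H = 8, seed = 1) {
  # two blobs separable by overall intensity
  with_seed(seed <- seed, NULL)
  set.seed(seed)
  y <- rep(c(0, 1), length.out = n)
  X <- array(rnorm(H * H * n * 3, sd = 0.1), c(H, H, n, 3))
  for (i in seq_len(n)) X[, , i, ] <- X[, , i, ] + y[i]
  list(x = X, y = y)
}

test_that("binary cross-entropy matches direct evaluation", {
  expect_equal(bce_loss(0.5, 1), log(2))
  expect_lt(bce_loss(1 - 1e-7, 1), 1e-6)
  expect_equal(bce_loss(0.9, 0), -log(0.1), tolerance = 1e-12)
  # clamping keeps the loss finite at the boundaries
  expect_true(is.finite(bce_loss(0, 1)) && is.finite(bce_loss(1, 0)))
  expect_equal(bce_loss(c(0.5, 0.5), c(1, 0)), log(2))
})

test_that("L2 penalty covers kernels only and vanishes iff they are zero", {
  net <- build_pneunet(pneunet_config(input_height = 8L, input_width = 8L),
                       seed = 2)
  expect_gt(l2_penalty(net, 0.001), 0)
  # biases and batch-norm parameters do not contribute
  before <- l2_penalty(net, 0.001)
  net$params$stem$b <- net$params$stem$b + 100
  net$params$stem_bn$gamma <- net$params$stem_bn$gamma * 3
  expect_equal(l2_penalty(net, 0.001), before)
  for (ke in pneunet:::kernel_elements(net$params))
    net$params[[ke[1]]][[ke[2]]][] <- 0
  expect_equal(l2_penalty(net, 0.001), 0)
})

test_that("early stopping counts patience from the last improvement", {
  # never triggers on a strictly improving trace
  expect_equal(early_stopping_trace(seq(1, 0.5, length.out = 50), 7),
               list(stopped_epoch = 50L, best_epoch = 50L))
  # hand-traced counter: best at 1, seven flat epochs trigger at 8
  expect_equal(early_stopping_trace(c(0.5, rep(0.6, 7)), 7),
               list(stopped_epoch = 8L, best_epoch = 1L))
  # seven consecutive epochs at or above the epoch-2 minimum trigger the
  # stop at epoch 9; the later 0.41 is never reached
  tr <- c(0.5, 0.4, 0.45, 0.44, 0.44, 0.44, 0.44, 0.44, 0.44, 0.41)
  expect_equal(early_stopping_trace(tr, 7),
               list(stopped_epoch = 9L, best_epoch = 2L))
  # with patience 8 the trigger moves to epoch 10; 0.41 never beats the
  # epoch-2 minimum, so the best epoch is unchanged
  expect_equal(early_stopping_trace(tr, 8),
               list(stopped_epoch = 10L, best_epoch = 2L))
  # ties do not count as improvement and the earliest minimum wins
  expect_equal(early_stopping_trace(c(0.3, 0.3, 0.3), 2),
               list(stopped_epoch = 3L, best_epoch = 1L))
  expect_error(early_stopping_trace(numeric(0), 3), "empty")
})

test_that("the published stop/best arithmetic holds on shaped traces", {
  # a 50-epoch-shaped trace whose minimum sits 7 epochs before the halt:
  # best + patience = stop (42 + 7 = 49)
  set.seed(6)
  tr <- c(seq(1.2, 0.44, length.out = 42), 0.44 + runif(8, 0.01, 0.05))
  out <- early_stopping_trace(tr, 7)
  expect_equal(out$best_epoch, 42L)
  expect_equal(out$stopped_epoch, 49L)
  expect_equal(out$stopped_epoch, out$best_epoch + 7L)
  # the pattern holds for any patience on that trace
  for (p in c(2L, 4L, 6L)) {
    o <- early_stopping_trace(tr, p)
    expect_equal(o$stopped_epoch, o$best_epoch + p)
  }
})

test_that("zero learning rate leaves weights untouched and history flat", {
  d <- tiny_data(6)
  data <- list(train = list(x = d$x[, , 1:4, , drop = FALSE], y = d$y[1:4]),
               val = list(x = d$x[, , 5:6, , drop = FALSE], y = d$y[5:6]))
  net <- build_pneunet(pneunet_config(input_height = 8L, input_width = 8L,
                                      dropout_rate = 0), seed = 3)
  w0 <- net$params
  fit <- train_pneunet(net, data,
                       train_config(learning_rate = 0, max_epochs = 3L,
                                    batch_size = 2L, seed = 1L))
  expect_equal(net$params, w0)
  expect_equal(fit$history$val_loss, rep(fit$history$val_loss[1], 3),
               tolerance = 1e-6)
})

test_that("training is deterministic under a fixed seed", {
  d <- tiny_data(6)
  data <- list(train = list(x = d$x[, , 1:4, , drop = FALSE], y = d$y[1:4]),
               val = list(x = d$x[, , 5:6, , drop = FALSE], y = d$y[5:6]))
  run <- function() {
    net <- build_pneunet(pneunet_config(input_height = 8L,
                                        input_width = 8L), seed = 3)
    train_pneunet(net, data, train_config(max_epochs = 2L, batch_size = 2L,
                                          seed = 11L))
  }
  f1 <- run(); f2 <- run()
  expect_identical(f1$history, f2$history)
  expect_identical(f1$checkpoint$weights, f2$checkpoint$weights)
})

test_that("the returned checkpoint reproduces the best validation loss", {
  d <- tiny_data(10)
  data <- list(train = list(x = d$x[, , 1:8, , drop = FALSE], y = d$y[1:8]),
               val = list(x = d$x[, , 9:10, , drop = FALSE], y = d$y[9:10]))
  net <- build_pneunet(pneunet_config(input_height = 8L, input_width = 8L),
                       seed = 4)
  fit <- train_pneunet(net, data, train_config(max_epochs = 4L,
                                               batch_size = 4L, seed = 2L))
  h <- fit$history
  best <- attr(h, "best_epoch")
  expect_equal(h$val_loss[best], min(h$val_loss))
  expect_equal(fit$checkpoint$val_loss_at_best, min(h$val_loss))
  # reloading the checkpoint and re-evaluating reproduces that loss
  net2 <- net_from_checkpoint(fit$checkpoint)
  p <- pneunet_forward(net2, data$val$x)
  expect_equal(bce_loss(p, data$val$y), min(h$val_loss), tolerance = 1e-6)
  # the recorded trace is self-consistent with the early-stopping rule
  es <- early_stopping_trace(h$val_loss, 7)
  expect_equal(es$best_epoch, best)
})

test_that("dropout is the only train/eval difference beyond batch norm", {
  net <- build_pneunet(pneunet_config(input_height = 8L, input_width = 8L,
                                      dropout_rate = 0), seed = 5)
  X <- tiny_data(4)$x
  # with rate 0 a training-mode forward consumes no randomness
  set.seed(99); before <- .Random.seed
  p_train <- pneunet_forward(net, X, training = TRUE)
  expect_identical(before, .Random.seed)
  # align the running statistics with the just-computed batch moments;
  # train- and eval-mode passes must then agree exactly
  for (nm in names(net$.cache)) {
    if (!is.list(net$.cache[[nm]])) next
    cb <- net$.cache[[nm]]$bn
    if (!is.null(cb)) {
      bn_name <- net$.cache[[nm]]$bn_name
      net$bn_state[[bn_name]]$mean <- cb$mu
      net$bn_state[[bn_name]]$var <- cb$v
    }
  }
  p_eval <- pneunet_forward(net, X, training = FALSE)
  expect_equal(p_train, p_eval, tolerance = 1e-12)
})

test_that("training aborts cleanly on bad input", {
  d <- tiny_data(4)
  net <- build_pneunet(pneunet_config(input_height = 8L, input_width = 8L),
                       seed = 6)
  expect_error(train_pneunet(net, list(train = list(x = NULL, y = NULL),
                                       val = d), train_config()),
               "empty training set")
})
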