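# Desk-scale study conditions shared by the end-to-end checks: the default
# synthetic dataset (200 images/class, seed 7), stratified 80-10-10 split,
# 24 px preprocessing, and the standard training recipe capped at 10
# epochs. The trained model is cached so several tests can share one run.

desk_cache <- new.env()

desk_dataset <- function() {
  if (is.null(desk_cache$data)) {
    recs <- generate_synthetic(synthetic_spec())
    labels <- vapply(recs, `[[`, "", "label")
    sp <- stratified_split(labels, split_spec(seed = 42))
    X <- records_to_tensor(recs, target = 24L)
    y <- attr(X, "labels")
    pick <- function(idx) list(x = X[, , idx, , drop = FALSE], y = y[idx])
    desk_cache$data <- list(train = pick(sp$train), val = pick(sp$val),
                            test = pick(sp$test))
  }
  desk_cache$data
}

desk_model <- function() {
  if (is.null(desk_cache$fit)) {
    data <- desk_dataset()
    net <- build_pneunet(pneunet_config(input_height = 24L,
                                        input_width = 24L), seed = 42)
    desk_cache$fit <- train_pneunet(net, data,
                                    train_config(max_epochs = 10L,
                                                 seed = 42L))
  }
  desk_cache$fit
}
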