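# Model checkpoints: the architecture config, all named weight arrays and
# batch-norm running statistics, plus the epoch bookkeeping that best-model
# selection produced. Saved as a single .rds archive with a human-readable
# JSON sidecar describing the architecture.

#' Create a checkpoint object from a network
#'
#' @param net A built network.
#' @param best_epoch Epoch at which the weights were captured.
#' @param val_loss_at_best Validation loss at that epoch.
#' @return A list of class `"pneunet_checkpoint"`.
#' @export
pneunet_checkpoint <- function(net, best_epoch = 1L,
                               val_loss_at_best = NA_real_) {
  structure(list(architecture = net$config,
                 weights = net$params,
                 bn_state = net$bn_state,
                 best_epoch = as.integer(best_epoch),
                 val_loss_at_best = val_loss_at_best),
            class = "pneunet_checkpoint")
}

#' Rebuild a network from a checkpoint
#'
#' @param ckpt A `"pneunet_checkpoint"` (or a path to one saved with
#'   [save_checkpoint()]).
#' @return A network environment ready for [pneunet_forward()].
#' @export
net_from_checkpoint <- function(ckpt) {
  if (is.character(ckpt)) ckpt <- load_checkpoint(ckpt)
  stopifnot(inherits(ckpt, "pneunet_checkpoint"))
  net <- build_pneunet(ckpt$architecture, seed = 0L)
  for (g in names(ckpt$weights)) {
    if (is.null(net$params[[g]]))
      stopf("checkpoint weight group '%s' does not fit the architecture", g)
    for (el in names(ckpt$weights[[g]])) {
      if (length(net$params[[g]][[el]]) != length(ckpt$weights[[g]][[el]]))
        stopf("weight '%s$%s' has the wrong shape for the architecture", g, el)
    }
  }
  net$params <- ckpt$weights
  net$bn_state <- ckpt$bn_state
  net
}

#' Save / load a checkpoint
#'
#' Writes the archive plus a `<path>.json` sidecar with the architecture as
#' structured text.
#'
#' @param ckpt A `"pneunet_checkpoint"`.
#' @param path Destination file (conventionally `.rds`).
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(ckpt, path) {
  stopifnot(inherits(ckpt, "pneunet_checkpoint"))
  saveRDS(ckpt, path)
  meta <- c(unclass(ckpt$architecture),
            list(best_epoch = ckpt$best_epoch,
                 val_loss_at_best = ckpt$val_loss_at_best))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stopf("checkpoint '%s' does not exist", path)
  ckpt <- readRDS(path)
  if (!inherits(ckpt, "pneunet_checkpoint"))
    stopf("'%s' is not a pneunet checkpoint", path)
  ckpt
}
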