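# Grad-CAM saliency over a spatial stage of the network (default: the
# pyramid-pooling fuse output, the final convolutional stage). Channel
# weights are the spatial means of the output-probability gradient; the map
# is the rectified weighted sum of activation channels, min-max normalized
# and bilinearly upsampled to input resolution.

#' Grad-CAM saliency map
#'
#' @param net A built (typically trained) network.
#' @param image A preprocessed input: a feature map `(H, W, 3)` from
#'   [preprocess()].
#' @param target_layer One of the spatial stages (`"stem"`, `"concat"`,
#'   `"se"`, `"down"`, `"aspp_fuse"`); default the final convolutional
#'   stage `"aspp_fuse"`.
#' @return A list of class `"gradcam_map"`: `heatmap` (matrix in `[0, 1]`
#'   at input resolution), `target_layer`, `class_index` (1 = pneumonia),
#'   `prob`, and `flat` (`TRUE` when the pre-normalization map was
#'   identically zero, in which case the heatmap is all zeros).
#' @export
grad_cam <- function(net, image, target_layer = "aspp_fuse") {
  if (!target_layer %in% PNEUNET_STAGES)
    stopf("unknown layer '%s'; available spatial stages: %s",
          target_layer, paste(PNEUNET_STAGES, collapse = ", "))
  if (length(dim(image)) == 3) {
    d_in <- dim(image)[1:2]
    X <- image; dim(X) <- c(dim(image)[1:2], 1L, dim(image)[3])
  } else {
    stopf("grad_cam expects a single feature map (H x W x C)")
  }
  prob <- pneunet_forward(net, X, training = FALSE)
  # gradient of the output probability w.r.t. the logit, then backward
  pneunet_backward(net, prob * (1 - prob))
  cm <- cam_from(net$acts[[target_layer]], net$stage_grads[[target_layer]])
  cam <- cm$cam; flat <- cm$flat
  if (!all(dim(cam) == d_in)) {
    cam <- EBImage::imageData(EBImage::resize(EBImage::Image(cam),
                                              w = d_in[1], h = d_in[2],
                                              filter = "bilinear"))
    cam <- pmax(cam, 0)
    # renormalize after interpolation so the peak is 1 at input resolution
    if (!flat && max(cam) > 0) cam <- cam / max(cam)
  }
  structure(list(heatmap = cam, target_layer = target_layer,
                 class_index = 1L, prob = prob, flat = flat),
            class = "gradcam_map")
}

# Rectified, min-max-normalized weighted channel sum: the saliency map
# proper. Invariant under positive rescaling of the activations.
cam_from <- function(act, grad) {
  da <- dim(act)                        # (H, W, 1, C)
  A <- act; dim(A) <- c(da[1] * da[2], da[4])
  G <- grad; dim(G) <- c(da[1] * da[2], da[4])
  w <- colMeans(G)                      # spatial mean of the gradient
  cam <- matrix(pmax(A %*% w, 0), da[1], da[2])
  mx <- max(cam)
  flat <- mx <= 0
  if (!flat) cam <- cam / mx
  list(cam = cam, flat = flat)
}

# Deterministic blue-cyan-yellow-red colormap on [0, 1].
cam_colormap <- function(v) {
  r <- clamp(1.5 - abs(4 * v - 3), 0, 1)
  g <- clamp(1.5 - abs(4 * v - 2), 0, 1)
  b <- clamp(1.5 - abs(4 * v - 1), 0, 1)
  list(r = r, g = g, b = b)
}

#' Overlay a saliency map on a radiograph
#'
#' Alpha-blends the colorized heatmap over the grayscale image.
#'
#' @param image Grayscale matrix in `[0, 1]` or `[0, 255]`, or a
#'   preprocessed feature map (first channel used).
#' @param cam A [grad_cam()] result (or a bare heatmap matrix in `[0, 1]`).
#' @param alpha Blend weight of the heatmap in `[0, 1]` (default 0.4);
#'   `alpha = 0` returns the gray image, `alpha = 1` the pure heatmap.
#' @return An `H x W x 3` RGB array in `[0, 1]`.
#' @export
overlay <- function(image, cam, alpha = 0.4) {
  if (alpha < 0 || alpha > 1) stopf("alpha must lie in [0, 1]")
  if (length(dim(image)) == 3) image <- image[, , 1]
  if (max(image) > 1) image <- image / 255
  hm <- if (inherits(cam, "gradcam_map")) cam$heatmap else cam
  if (!all(dim(image) == dim(hm)))
    stopf("image (%dx%d) and heatmap (%dx%d) shapes differ",
          nrow(image), ncol(image), nrow(hm), ncol(hm))
  col <- cam_colormap(hm)
  out <- array(0, c(dim(image), 3L))
  out[, , 1] <- (1 - alpha) * image + alpha * col$r
  out[, , 2] <- (1 - alpha) * image + alpha * col$g
  out[, , 3] <- (1 - alpha) * image + alpha * col$b
  clamp(out, 0, 1)
}

#' Mean heatmap contrast inside vs outside ground-truth opacity masks
#'
#' Localization score used to validate saliency on synthetic data: the mean
#' Grad-CAM value inside the generator's ground-truth opacity masks versus
#' outside (within the image), averaged over records.
#'
#' @param net A trained network.
#' @param records Synthetic pneumonia image records carrying
#'   `opacity_mask`.
#' @param target Preprocessing resolution fed to the network.
#' @param target_layer Stage passed to [grad_cam()].
#' @return List with `inside`, `outside` (mean heatmap values) and
#'   `n_images`.
#' @export
gradcam_localization <- function(net, records, target = 32L,
                                 target_layer = "aspp_fuse") {
  records <- Filter(function(r) !is.null(r$opacity_mask) &&
                      any(r$opacity_mask), records)
  if (length(records) == 0) stopf("no records with opacity masks")
  ins <- outs <- numeric(length(records))
  for (i in seq_along(records)) {
    r <- records[[i]]
    fm <- preprocess(r, target = target)
    cam <- grad_cam(net, fm, target_layer = target_layer)
    mask <- EBImage::imageData(EBImage::resize(
      EBImage::Image(r$opacity_mask * 1), w = target, h = target,
      filter = "bilinear")) > 0.5
    if (!any(mask) || all(mask)) { ins[i] <- NA; outs[i] <- NA; next }
    ins[i] <- mean(cam$heatmap[mask])
    outs[i] <- mean(cam$heatmap[!mask])
  }
  list(inside = mean(ins, na.rm = TRUE), outside = mean(outs, na.rm = TRUE),
       n_images = sum(!is.na(ins)))
}
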