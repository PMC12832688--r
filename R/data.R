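# Image ingestion and preprocessing: class-per-folder directory loading
# (the public chest X-ray dataset convention) and the resize/grayscale/
# normalize pipeline feeding the network.

PNEUNET_LABELS <- c("normal", "pneumonia")

#' Construct an image record
#'
#' @param identifier Record id string.
#' @param pixels 2-D numeric matrix of 8-bit intensities in `[0, 255]`.
#' @param label `"normal"` or `"pneumonia"`.
#' @return A list of class `"image_record"`.
#' @export
image_record <- function(identifier, pixels, label) {
  if (is.null(pixels) || length(pixels) == 0)
    stopf("image '%s' is empty", identifier)
  if (min(pixels) < 0 || max(pixels) > 255)
    stopf("image '%s' has intensities outside [0, 255]", identifier)
  label <- match.arg(tolower(label), PNEUNET_LABELS)
  structure(list(identifier = identifier, pixels = pixels, label = label),
            class = "image_record")
}

rgb_to_luminance <- function(a) {
  0.299 * a[, , 1] + 0.587 * a[, , 2] + 0.114 * a[, , 3]
}

#' Preprocess an image for the network
#'
#' Bilinear resize to `target x target`, grayscale conversion (Rec. 601
#' luminance for RGB inputs), intensity scaling to `[0, 1]`, and replication
#' of the gray plane to three identical channels (the network stem expects
#' three input channels). Resizing an already-conforming image is the
#' identity.
#'
#' @param record An [image_record()], or a bare matrix / `H x W x 3` array
#'   of intensities in `[0, 255]`.
#' @param target Output side length in pixels (default 224).
#' @return A [feature_map()] of shape `target x target x 3` with all three
#'   channels identical.
#' @export
preprocess <- function(record, target = 224L) {
  px <- if (inherits(record, "image_record") || (is.list(record) &&
                                                 !is.null(record$pixels)))
    record$pixels else record
  id <- if (is.list(record) && !is.null(record$identifier))
    record$identifier else "<array>"
  if (is.null(px) || !is.numeric(px) || length(px) == 0)
    stopf("image '%s' is empty or unreadable", id)
  if (length(dim(px)) == 3) px <- rgb_to_luminance(px)
  g <- px / 255
  if (nrow(g) != target || ncol(g) != target) {
    scale <- max(nrow(g), ncol(g)) / target
    # anti-aliasing prefilter for downscaling: without it, bilinear
    # decimation samples 2x2 neighborhoods and aliases away structures
    # smaller than the sampling stride
    if (scale > 1) g <- gaussian_blur(g, sigma = 0.5 * scale)
    g <- EBImage::imageData(EBImage::resize(EBImage::Image(g),
                                            w = target, h = target,
                                            filter = "bilinear"))
    g <- clamp(g, 0, 1)
  }
  feature_map(array(rep(as.numeric(g), 3), c(target, target, 3L)))
}

read_image_file <- function(path) {
  ext <- tolower(tools::file_ext(path))
  a <- switch(ext,
    png = png::readPNG(path),
    jpg = , jpeg = {
      if (!requireNamespace("jpeg", quietly = TRUE))
        stopf("reading '%s' requires the jpeg package", path)
      jpeg::readJPEG(path)
    },
    stopf("unsupported image format '%s' (expected png/jpg/jpeg)", ext))
  if (length(dim(a)) == 3) {
    if (dim(a)[3] >= 3) a <- rgb_to_luminance(a[, , 1:3, drop = FALSE])
    else a <- a[, , 1]
  }
  round(a * 255)
}

#' Load a class-per-folder image directory
#'
#' Reads every PNG/JPEG under `root/<label>/` into image records, labeled by
#' the (case-insensitive) subdirectory name, in deterministic lexicographic
#' order.
#'
#' @param root Directory containing one subdirectory per class label
#'   (`normal`, `pneumonia`).
#' @return List of [image_record()]s.
#' @export
load_directory <- function(root) {
  if (!dir.exists(root)) stopf("data directory '%s' does not exist", root)
  subs <- sort(list.dirs(root, recursive = FALSE))
  subs <- subs[!tolower(basename(subs)) %in% "manifest"]
  if (length(subs) == 0) {
    warning(sprintf("'%s' contains no class subdirectories", root))
    return(list())
  }
  bad <- subs[!tolower(basename(subs)) %in% PNEUNET_LABELS]
  if (length(bad))
    stopf("unknown class directory '%s'; expected one of: %s",
          basename(bad[1]), paste(PNEUNET_LABELS, collapse = ", "))
  recs <- list()
  for (s in subs) {
    label <- tolower(basename(s))
    files <- sort(list.files(s, pattern = "\\.(png|jpe?g)$",
                             ignore.case = TRUE, full.names = TRUE))
    for (f in files) {
      px <- tryCatch(read_image_file(f),
                     error = function(e) stopf("cannot read '%s': %s",
                                               f, conditionMessage(e)))
      recs[[length(recs) + 1L]] <-
        image_record(tools::file_path_sans_ext(basename(f)), px, label)
    }
  }
  if (length(recs) == 0)
    warning(sprintf("'%s' contains no readable images", root))
  recs
}

#' Preprocess a list of records into a batch tensor
#'
#' @param records List of image records.
#' @param target Side length passed to [preprocess()].
#' @return A 4-D array `(target, target, N, 3)` plus a `labels` attribute
#'   (integer, 1 = pneumonia).
#' @export
records_to_tensor <- function(records, target = 224L) {
  X <- stack_feature_maps(lapply(records, preprocess, target = target))
  attr(X, "labels") <- as.integer(vapply(records, `[[`, "", "label") ==
                                    "pneumonia")
  X
}
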