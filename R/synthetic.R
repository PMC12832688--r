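# Seed-controlled synthetic chest-radiograph generator. Emulates grayscale
# frontal radiographs at desk scale: a brighter thorax background carrying
# two darker elliptical lung fields, with the pneumonia class adding blurred
# bright opacity blobs confined to the lung fields, plus additive Gaussian
# pixel noise. Ground-truth opacity masks are retained so interpretability
# tests can score localization against construction.

#' Synthetic radiograph specification
#'
#' All images share the same deterministic anatomy (background plus lung
#' fields); each image receives its own noise field. With
#' `opacity_intensity = 0` and `noise_sd = 0` the two classes are therefore
#' pixel-identical.
#'
#' @param n_normal,n_pneumonia Images per class (default 200 each).
#' @param image_size Square image side in pixels (default 224).
#' @param lung_ellipses List of two `(center, axes)` pairs in coordinates
#'   relative to the image side; defaults place two vertical ellipses in the
#'   mid-thorax.
#' @param background_intensity Thorax background gray level (default 200).
#' @param lung_darkening Intensity subtracted inside the lung fields
#'   (default 90, giving aerated-lung gray ~110).
#' @param opacity_count Integer range `c(min, max)` of opacity blobs per
#'   pneumonia image (default 1-3).
#' @param opacity_intensity Peak added intensity of a blob before blurring
#'   (default 70).
#' @param opacity_sigma Gaussian blur of the blobs, pixels (default 6).
#' @param noise_sd Additive Gaussian pixel noise standard deviation
#'   (default 8).
#' @param seed Integer seed; fully determines every image.
#' @return A list of class `"synthetic_spec"`.
#' @export
synthetic_spec <- function(n_normal = 200L, n_pneumonia = 200L,
                           image_size = 224L,
                           lung_ellipses = list(
                             list(center = c(0.35, 0.52), axes = c(0.16, 0.30)),
                             list(center = c(0.65, 0.52), axes = c(0.16, 0.30))),
                           background_intensity = 200,
                           lung_darkening = 90,
                           opacity_count = c(1L, 3L),
                           opacity_intensity = 70,
                           opacity_sigma = 6,
                           noise_sd = 8,
                           seed = 7L) {
  if (!is_count(n_normal) || !is_count(n_pneumonia) || !is_count(image_size))
    stopf("n_normal, n_pneumonia and image_size must be positive integers")
  for (e in lung_ellipses)
    if (any(e$axes <= 0)) stopf("degenerate lung geometry: axes must be > 0")
  if (length(opacity_count) == 1L) opacity_count <- rep(opacity_count, 2L)
  if (opacity_count[1] < 1 || opacity_count[2] < opacity_count[1])
    stopf("opacity_count must be a positive integer range c(min, max)")
  if (noise_sd < 0 || opacity_sigma <= 0)
    stopf("noise_sd must be >= 0 and opacity_sigma > 0")
  structure(list(n_normal = as.integer(n_normal),
                 n_pneumonia = as.integer(n_pneumonia),
                 image_size = as.integer(image_size),
                 lung_ellipses = lung_ellipses,
                 background_intensity = background_intensity,
                 lung_darkening = lung_darkening,
                 opacity_count = as.integer(opacity_count),
                 opacity_intensity = opacity_intensity,
                 opacity_sigma = opacity_sigma,
                 noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

gaussian_blur <- function(m, sigma) {
  # brush must stay odd and no larger than the image
  r <- min(2L * as.integer(ceiling(3 * sigma)) + 1L,
           min(dim(m)) - (min(dim(m)) + 1L) %% 2L)
  EBImage::imageData(EBImage::gblur(EBImage::Image(m), sigma = sigma,
                                    radius = r))
}

# Derive a per-image 31-bit seed from the spec seed and an image index.
derive_seed <- function(seed, idx, stream = 0) {
  as.integer((abs(as.numeric(seed)) * 1000003 + idx * 131 + stream) %%
               2147483629)
}

lung_field_mask <- function(spec) {
  S <- spec$image_size
  xs <- (seq_len(S) - 0.5) / S
  mask <- matrix(FALSE, S, S)   # rows = y, cols = x
  for (e in spec$lung_ellipses) {
    dx2 <- outer(rep(1, S), ((xs - e$center[1]) / e$axes[1])^2)
    dy2 <- outer(((xs - e$center[2]) / e$axes[2])^2, rep(1, S))
    mask <- mask | (dx2 + dy2 <= 1)
  }
  mask
}

#' Generate a synthetic radiograph dataset
#'
#' @param spec A [synthetic_spec()].
#' @return List of image records (`identifier`, `pixels` — integer matrix in
#'   `[0, 255]` —, `label`, and for pneumonia images `opacity_mask`, the
#'   ground-truth logical mask of opacity pixels). The shared lung-field
#'   mask is attached as attribute `"lung_mask"`.
#' @export
generate_synthetic <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  S <- spec$image_size
  lung <- lung_field_mask(spec)
  lung_idx <- which(lung)
  anatomy <- matrix(spec$background_intensity, S, S) -
    spec$lung_darkening * lung
  anatomy <- gaussian_blur(anatomy, sigma = max(2, S / 112))

  make_image <- function(i, gi, label) {
    opac <- NULL
    mask <- NULL
    if (label == "pneumonia") {
      opac <- with_seed(derive_seed(spec$seed, i, stream = 1), {
        acc <- matrix(0, S, S)
        n_op <- sample(seq(spec$opacity_count[1], spec$opacity_count[2]), 1L)
        for (k in seq_len(n_op)) {
          ctr <- lung_idx[sample(length(lung_idx), 1L)]
          cy <- (ctr - 1L) %% S + 1L
          cx <- (ctr - 1L) %/% S + 1L
          rad <- stats::runif(1, 0.04, 0.09) * S
          d2 <- outer((seq_len(S) - cy)^2, (seq_len(S) - cx)^2, `+`)
          acc[d2 <= rad^2] <- spec$opacity_intensity
        }
        acc
      })
      opac <- gaussian_blur(opac, spec$opacity_sigma) * lung
      mask <- opac > 0.25 * spec$opacity_intensity
    }
    img <- anatomy
    if (!is.null(opac)) img <- img + opac
    # noise streams are keyed by the global image index so no two images
    # (within or across classes) share a noise field
    if (spec$noise_sd > 0)
      img <- img + with_seed(derive_seed(spec$seed, gi, stream = 2),
                             matrix(stats::rnorm(S * S, sd = spec$noise_sd),
                                    S, S))
    px <- matrix(as.integer(round(clamp(img, 0, 255))), S, S)
    rec <- list(identifier = sprintf("%s_%04d", label, i),
                pixels = px, label = label)
    if (!is.null(mask)) rec$opacity_mask <- mask
    rec
  }

  recs <- c(lapply(seq_len(spec$n_normal),
                   function(i) make_image(i, i, "normal")),
            lapply(seq_len(spec$n_pneumonia),
                   function(i) make_image(i, spec$n_normal + i,
                                          "pneumonia")))
  attr(recs, "lung_mask") <- lung
  recs
}

#' Write an image dataset in class-per-folder layout
#'
#' Writes one PNG per record under `<dir>/<label>/` plus a `manifest.csv`
#' (`identifier`, `label`, `file`) — the layout [load_directory()] reads.
#'
#' @param records List of image records.
#' @param dir Output directory (created if needed).
#' @return The manifest data frame, invisibly.
#' @export
write_dataset <- function(records, dir) {
  rows <- lapply(records, function(r) {
    sub <- file.path(dir, r$label)
    dir.create(sub, recursive = TRUE, showWarnings = FALSE)
    f <- file.path(sub, paste0(r$identifier, ".png"))
    png::writePNG(r$pixels / 255, f)
    data.frame(identifier = r$identifier, label = r$label,
               file = file.path(r$label, basename(f)),
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}
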