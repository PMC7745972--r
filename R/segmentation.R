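# coerce an RGB raster (array W x H x 3, values in [0,1] or 0-255, or an
# EBImage Image) to a W x H x 3 array in [0,1]
as_rgb_array <- function(image) {
  if (inherits(image, "Image")) image <- EBImage::imageData(image)
  d <- dim(image)
  if (length(d) != 3 || d[3] != 3)
    stop("expected a 3-channel RGB raster, got ",
         if (length(d) == 3) paste0(d[3], " channel(s)") else "a non-3D array")
  if (max(image) > 1 + 1e-9) image <- image / 255
  image
}

#' CIELAB b channel of an RGB image, rescaled to 0-255
#'
#' Converts sRGB to CIELAB (D65) and returns the b axis — the blue-yellow
#' opponent channel, low for blue pixels and high for yellow — shifted by
#' +128 and clipped to the 0-255 level range, so a neutral gray sits at 128.
#' Against a blue keying background, plant and soil pixels are bright on
#' this channel while the background is dark.
#'
#' @param image RGB raster: numeric array width x height x 3 (values in
#'   \[0,1\] or 0-255) or an `EBImage::Image`.
#' @return numeric width x height matrix of levels in \[0, 255\].
#' @export
b_channel <- function(image) {
  image <- as_rgb_array(image)
  d <- dim(image)
  rgb <- cbind(as.vector(image[, , 1]), as.vector(image[, , 2]),
               as.vector(image[, , 3]))
  lab <- grDevices::convertColor(rgb, from = "sRGB", to = "Lab")
  b <- matrix(lab[, 3] + 128, d[1], d[2])
  b[b < 0] <- 0; b[b > 255] <- 255
  b
}

#' Binary chroma-key mask from the b channel
#'
#' Pixels with `b < threshold` are background (0); the rest are foreground
#' (1). With `threshold = "otsu"` the level is chosen automatically by
#' Otsu's method on the channel histogram.
#'
#' @param b numeric matrix of levels in \[0, 255\] from [b_channel()].
#' @param threshold numeric level in \[0, 256\], or `"otsu"`.
#' @return binary matrix (0/1) of the same dimensions, class `mask_image`.
#' @export
threshold_mask <- function(b, threshold = "otsu") {
  if (identical(threshold, "otsu") || identical(threshold, "auto")) {
    threshold <- 255 * EBImage::otsu(EBImage::Image(b / 255), range = c(0, 1))
  }
  stopifnot(is.numeric(threshold), length(threshold) == 1,
            threshold >= 0, threshold <= 256)
  structure((b >= threshold) * 1L, class = "mask_image")
}

#' Morphological cleanup of a binary mask
#'
#' Applies the requested operations in order: `dilate` and `erode` with a
#' disc structuring element of the given size, `fill_holes`, and `blur` —
#' Gaussian smoothing followed by re-binarization at 0.5. The default
#' sequence dilate(3), fill_holes, erode(3), blur(sigma = 1) closes small
#' gaps, removes pinholes, and smooths the mask edge left by thresholding.
#'
#' @param mask binary matrix (0/1).
#' @param ops character vector, ordered subset of
#'   `c("dilate", "fill_holes", "erode", "blur")` (repeats allowed).
#' @param sizes numeric vector parallel to `ops`: brush diameter in pixels
#'   for dilate/erode, Gaussian sigma for blur, ignored for fill_holes.
#' @return cleaned binary matrix, class `mask_image`.
#' @export
cleanup <- function(mask, ops = c("dilate", "fill_holes", "erode", "blur"),
                    sizes = c(3, NA, 3, 1)) {
  stopifnot(length(sizes) == length(ops))
  m <- EBImage::Image(unclass(mask) * 1)
  for (i in seq_along(ops)) {
    op <- ops[i]; sz <- sizes[i]
    m <- switch(op,
      dilate = EBImage::dilate(m, EBImage::makeBrush(as.integer(sz), shape = "disc")),
      erode = EBImage::erode(m, EBImage::makeBrush(as.integer(sz), shape = "disc")),
      fill_holes = EBImage::fillHull(m),
      blur = {
        bl <- EBImage::gblur(m, sigma = sz)
        EBImage::Image((EBImage::imageData(bl) >= 0.5) * 1)
      },
      stop("unknown cleanup operation: ", op)
    )
  }
  structure((EBImage::imageData(m) > 0.5) * 1L, class = "mask_image")
}

#' Replace the keyed-out background of an image
#'
#' Foreground pixels (mask 1) are taken from `image`, background pixels
#' (mask 0) from `new_background`.
#'
#' @param image,new_background RGB rasters of identical dimensions.
#' @param mask binary matrix matching the rasters' width x height.
#' @return composited RGB array.
#' @export
replace_background <- function(image, mask, new_background) {
  image <- as_rgb_array(image); new_background <- as_rgb_array(new_background)
  mask <- unclass(mask)
  if (!identical(dim(image), dim(new_background)) ||
      !identical(dim(mask), dim(image)[1:2]))
    stop("dimension mismatch between image, mask, and new background")
  out <- image
  for (ch in 1:3)
    out[, , ch] <- image[, , ch] * mask + new_background[, , ch] * (1 - mask)
  out
}

#' Foreground mask by background subtraction
#'
#' Differences an image against a plant-free capture from the identical
#' pose: pixels whose maximal per-channel absolute difference exceeds
#' `tolerance` levels (on the 0-255 scale) are foreground.
#'
#' @param image,background_only RGB rasters of identical dimensions.
#' @param tolerance per-channel difference in levels; 0 marks any differing
#'   pixel as foreground (exact on lossless rasters).
#' @return binary matrix, class `mask_image`.
#' @export
background_subtract <- function(image, background_only, tolerance = 0) {
  image <- as_rgb_array(image); background_only <- as_rgb_array(background_only)
  if (!identical(dim(image), dim(background_only)))
    stop("dimension mismatch between image and background-only image")
  dmax <- pmax(abs(image[, , 1] - background_only[, , 1]),
               abs(image[, , 2] - background_only[, , 2]),
               abs(image[, , 3] - background_only[, , 3])) * 255
  structure((dmax > tolerance) * 1L, class = "mask_image")
}

#' Batch chroma-key segmentation of image files
#'
#' Reads each input image, computes the b-channel mask (optionally cleaned
#' up), writes it as an 8-bit 0/255 PNG next to the requested output
#' directory, and optionally writes a background-replaced composite.
#'
#' @param inputs character vector of image paths (PNG/JPEG).
#' @param out_dir output directory (created if needed).
#' @param threshold level in \[0,256\] or `"otsu"`.
#' @param clean logical: apply the default [cleanup()] sequence.
#' @param new_background optional path of a replacement background image
#'   (resized not supported: must match each input's dimensions).
#' @return invisibly, data.frame of input and mask paths.
#' @export
segment_batch <- function(inputs, out_dir, threshold = "otsu", clean = TRUE,
                          new_background = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  bg <- if (!is.null(new_background)) as_rgb_array(EBImage::readImage(new_background))
  res <- lapply(inputs, function(f) {
    img <- as_rgb_array(EBImage::readImage(f))
    mask <- threshold_mask(b_channel(img), threshold)
    if (clean) mask <- cleanup(mask)
    stem <- tools::file_path_sans_ext(basename(f))
    mask_path <- file.path(out_dir, paste0(stem, "-mask.png"))
    EBImage::writeImage(EBImage::Image(unclass(mask) * 1), mask_path)
    if (!is.null(bg)) {
      comp <- replace_background(img, mask, bg)
      EBImage::writeImage(EBImage::Image(comp, colormode = "Color"),
                          file.path(out_dir, paste0(stem, "-composite.png")))
    }
    data.frame(input = f, mask = mask_path, stringsAsFactors = FALSE)
  })
  invisible(do.call(rbind, res))
}
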