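#' Construct a fluorescence image object
#'
#' A `fluor_image` bundles one grayscale microscopy frame (pixel intensities
#' normalized to `[0, 1]`) with the physical pixel pitch and channel metadata.
#' It is the unit of input for segmentation, cropping and rendering.
#'
#' Pixel coordinates are 0-based, row-major, origin at the top-left corner;
#' `pixels[i, j]` is the pixel in (0-based) row `i - 1`, column `j - 1`.
#'
#' @param pixels Numeric matrix of intensities in `[0, 1]` (rows = image rows).
#' @param pitch_um_per_px Physical pixel pitch in micrometres per pixel
#'   (`> 0`). The imager this pipeline models resolves ~1 um over ~2.7 pixels,
#'   i.e. a pitch of about 0.37 um/px.
#' @param channel One of `"glucose_like"` (2-NBDG-style green channel),
#'   `"mmp_like"` (TMRE-style red channel) or `"other"`.
#' @param image_id Character identifier used to tag downstream cell records.
#'
#' @return An object of class `fluor_image`.
#' @export
fluor_image <- function(pixels, pitch_um_per_px, channel = "other",
                        image_id = "image") {
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    abort("`pixels` must be a numeric matrix.")
  }
  if (nrow(pixels) < 1L || ncol(pixels) < 1L) {
    abort("image must have height and width >= 1.")
  }
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 1) {
    abort("all pixel values must lie in [0, 1].")
  }
  if (!is.numeric(pitch_um_per_px) || length(pitch_um_per_px) != 1L ||
      pitch_um_per_px <= 0) {
    abort("`pitch_um_per_px` must be a single positive number.")
  }
  channel <- match.arg(channel, c("glucose_like", "mmp_like", "other"))
  structure(
    list(
      pixels = pixels,
      pitch_um_per_px = as.numeric(pitch_um_per_px),
      channel = channel,
      image_id = as.character(image_id)
    ),
    class = "fluor_image"
  )
}

#' @export
print.fluor_image <- function(x, ...) {
  cat(sprintf(
    "<fluor_image> %s: %d x %d px, pitch %.4f um/px, channel %s, range [%.4g, %.4g]\n",
    x$image_id, nrow(x$pixels), ncol(x$pixels), x$pitch_um_per_px,
    x$channel, min(x$pixels), max(x$pixels)
  ))
  invisible(x)
}

#' @export
dim.fluor_image <- function(x) dim(x$pixels)

#' Read a grayscale microscopy image
#'
#' Reads a grayscale TIFF or PNG into a [fluor_image]. Integer pixel data are
#' rescaled to `[0, 1]` by dividing by the type's full-scale value (255 for
#' 8-bit, 65535 for 16-bit); floating-point data are clipped to `[0, 1]`.
#' Normalizing by the container's full scale (rather than each image's own
#' maximum) preserves intensity comparability across images acquired at fixed
#' gain, contrast and illumination.
#'
#' @param path Path to a grayscale TIFF (preferred) or PNG file.
#' @param pitch_um_per_px Physical pixel pitch in um/px.
#' @param channel Channel tag, see [fluor_image()].
#' @param image_id Identifier; defaults to the file name without extension.
#' @param channel_index For multi-channel files, which plane to extract.
#'   Without it a color image is an error: silently collapsing channels would
#'   corrupt single-dye intensity measurements.
#'
#' @return A [fluor_image].
#' @export
read_image <- function(path, pitch_um_per_px, channel = "other",
                       image_id = NULL, channel_index = NULL) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
    tif = ,
    tiff = tiff::readTIFF(path),
    png = png::readPNG(path),
    abort(paste0("unsupported image format: .", ext, " (use TIFF or PNG)"))
  )
  if (is.list(px)) px <- px[[1L]]
  if (length(dim(px)) == 3L) {
    if (is.null(channel_index)) {
      abort("multi-channel image: supply `channel_index` to pick one plane.")
    }
    px <- px[, , channel_index]
  }
  # readTIFF/readPNG already divide integer data by the dtype full scale;
  # float data may legitimately stray outside [0,1] and is clipped.
  px <- pmin(pmax(px, 0), 1)
  if (is.null(image_id)) image_id <- tools::file_path_sans_ext(basename(path))
  fluor_image(px, pitch_um_per_px, channel, image_id)
}

#' Write a fluorescence image as TIFF
#'
#' Writes the normalized pixel matrix as a 32-bit float TIFF so that reading
#' it back reproduces the values to float32 precision.
#'
#' @param image A [fluor_image].
#' @param path Output path (`.tif`).
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  stopifnot(inherits(image, "fluor_image"))
  tiff::writeTIFF(image$pixels, path, bits.per.sample = 32L)
  invisible(path)
}

#' Read or write a label mask as 16-bit TIFF
#'
#' Label masks hold one positive integer per segmented object and 0 for
#' background. They are stored as 16-bit grayscale TIFF (labels divided by
#' 65535), which bounds the number of objects per image at 65535.
#'
#' @param mask Integer matrix of labels (0 = background).
#' @param path File path.
#' @return `write_label_mask()`: `path`, invisibly. `read_label_mask()`: an
#'   integer label matrix.
#' @export
write_label_mask <- function(mask, path) {
  stopifnot(is.matrix(mask), max(mask) <= 65535L, min(mask) >= 0L)
  tiff::writeTIFF(mask / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_label_mask
#' @export
read_label_mask <- function(path) {
  m <- tiff::readTIFF(path)
  matrix(as.integer(round(m * 65535)), nrow(m), ncol(m))
}
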