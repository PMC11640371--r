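#' @keywords internal
"_PACKAGE"

# Axis convention shared by every module: images are base-R numeric arrays of
# dimension height x width x 3 (rows = image rows), channel order R, G, B,
# 8-bit intensities stored as integer-valued doubles in [0, 255].

#' Validate an RGB image array
#'
#' Checks the package-wide image contract: a 3-dimensional numeric array of
#' shape height x width x 3 with all intensities in \[0, 255\].
#'
#' @param img Object to validate.
#' @param arg Name used in error messages.
#' @return The image, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_rgb_image <- function(img, arg = "img") {
  if (!is.array(img) || length(dim(img)) != 3L) {
    stop(sprintf("`%s` must be a 3-d array (height x width x 3)", arg), call. = FALSE)
  }
  d <- dim(img)
  if (d[3] != 3L) {
    stop(sprintf("`%s` must have exactly 3 channels, got %d", arg, d[3]), call. = FALSE)
  }
  if (d[1] < 1L || d[2] < 1L) {
    stop(sprintf("`%s` must have height >= 1 and width >= 1", arg), call. = FALSE)
  }
  if (anyNA(img) || min(img) < 0 || max(img) > 255) {
    stop(sprintf("`%s` intensities must lie in [0, 255]", arg), call. = FALSE)
  }
  invisible(img)
}

#' @rdname validate_rgb_image
#' @export
is_rgb_image <- function(img) {
  is.array(img) && length(dim(img)) == 3L && dim(img)[3] == 3L &&
    !anyNA(img) && min(img) >= 0 && max(img) <= 255
}

# Round half away from zero, then clamp to the 8-bit range. Used after every
# arithmetic image step so the [0, 255] invariant can never be violated.
clip8 <- function(x) {
  pmin(pmax(sign(x) * floor(abs(x) + 0.5), 0), 255)
}

# height x width x 3 in [0,255]  ->  EBImage Image (x = width first), [0,1]
to_ebimage <- function(img) {
  EBImage::Image(aperm(img, c(2L, 1L, 3L)) / 255, colormode = "Color")
}

# EBImage Image -> height x width x 3 array in [0,255], re-quantized to 8 bit
from_ebimage <- function(e) {
  a <- EBImage::imageData(e)
  if (length(dim(a)) == 2L) a <- array(a, c(dim(a), 3L))
  clip8(aperm(a, c(2L, 1L, 3L)) * 255)
}

#' Read an image file as an RGB array
#'
#' PNG files are read with the \pkg{png} package; other raster formats
#' (e.g. JPEG, TIFF) are delegated to [EBImage::readImage()]. Grayscale
#' images are expanded to three identical channels; an alpha channel, if
#' present, is dropped.
#'
#' @param path Path to a PNG or JPEG image.
#' @return A height x width x 3 array with intensities in \[0, 255\].
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("image file not found: ", path, call. = FALSE)
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    a <- png::readPNG(path)
    if (length(dim(a)) == 2L) a <- array(a, c(dim(a), 1L))
    if (dim(a)[3] == 1L) a <- a[, , c(1L, 1L, 1L), drop = FALSE]
    if (dim(a)[3] == 4L) a <- a[, , 1:3, drop = FALSE]
    img <- clip8(a * 255)
  } else {
    img <- from_ebimage(EBImage::readImage(path))
  }
  validate_rgb_image(img, "read image")
  img
}

#' Write an RGB array to an image file
#'
#' @param img A height x width x 3 array in \[0, 255\].
#' @param path Output path; `.png` uses \pkg{png}, other extensions use
#'   [EBImage::writeImage()].
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  validate_rgb_image(img)
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::writePNG(img / 255, path)
  } else {
    EBImage::writeImage(to_ebimage(img), path)
  }
  invisible(path)
}

#' Resize an RGB image
#'
#' Bilinear resampling via [EBImage::resize()], followed by re-quantization
#' to 8-bit. The size arguments follow the width x height convention used for
#' image dimensions (a "700 x 600" target produces an array with 600 rows and
#' 700 columns).
#'
#' @param img A height x width x 3 array in \[0, 255\].
#' @param width,height Target size in pixels.
#' @return The resized image array (`height` rows, `width` columns).
#' @export
resize_image <- function(img, width, height) {
  validate_rgb_image(img)
  stopifnot(width >= 1, height >= 1)
  from_ebimage(EBImage::resize(to_ebimage(img), w = width, h = height))
}

#' The fixed 256-entry HOT lookup table
#'
#' A black - red - yellow - white ramp, defined arithmetically so that mapped
#' output is bit-exact across platforms and independent of any plotting
#' library's palette: for t = i/255, R = clip(3t), G = clip(3t - 1),
#' B = clip(3t - 2), each scaled to \[0, 255\] and rounded.
#'
#' @return A 256 x 3 integer-valued matrix (rows = input intensity 0..255,
#'   columns = R, G, B).
#' @export
hot_colormap <- function() {
  t <- (0:255) / 255
  cbind(
    R = clip8(pmin(pmax(3 * t, 0), 1) * 255),
    G = clip8(pmin(pmax(3 * t - 1, 0), 1) * 255),
    B = clip8(pmin(pmax(3 * t - 2, 0), 1) * 255)
  )
}
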