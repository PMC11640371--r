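# Fluorescence-simulation preprocessing: a deterministic channel-arithmetic
# transform that amplifies the green channel (where fundus pathology contrast
# lives), optionally suppresses blue, and optionally renders the result
# through a fixed HOT colormap. This is not angiography physics; it is a
# reproducible image-enhancement step applied before feature extraction.

#' Configuration for the fluorescence-simulation transform
#'
#' @param alpha Positive green-channel scaling factor. The conventional
#'   default is 2.0, which doubles green intensity (saturating at 255).
#' @param suppress_blue If `TRUE` (default), the blue channel of the output
#'   is set to zero so the amplified green reads as fluorescence.
#' @param colormap Either `"none"` (default; classification path) or `"HOT"`,
#'   which renders the processed green channel through [hot_colormap()]
#'   (visualization branch).
#' @return A list of class `fluorescence_config`.
#' @export
fluorescence_config <- function(alpha = 2.0, suppress_blue = TRUE,
                                colormap = c("none", "HOT")) {
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) || alpha <= 0) {
    stop("`alpha` must be a single positive number", call. = FALSE)
  }
  colormap <- match.arg(toupper(colormap[1]), c("NONE", "HOT"))
  structure(
    list(alpha = alpha, suppress_blue = isTRUE(suppress_blue),
         colormap = if (colormap == "NONE") "none" else "HOT"),
    class = "fluorescence_config"
  )
}

#' Split an RGB image into its three channel grids
#'
#' @param img A height x width x 3 array in \[0, 255\].
#' @return A named list with matrices `R`, `G`, `B` of the same spatial shape.
#' @export
split_channels <- function(img) {
  validate_rgb_image(img)
  list(R = img[, , 1, drop = TRUE], G = img[, , 2, drop = TRUE],
       B = img[, , 3, drop = TRUE])
}

#' Amplify a green-channel grid
#'
#' Applies `G' = alpha * G` elementwise, rounds half away from zero, and
#' clips at the 8-bit maximum of 255.
#'
#' @param channel_g A matrix (or array slice) of intensities in \[0, 255\].
#' @param alpha Positive scaling factor.
#' @return The scaled grid, same shape, values in \[0, 255\].
#' @export
enhance_green <- function(channel_g, alpha = 2.0) {
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) || alpha <= 0) {
    stop("`alpha` must be a single positive number", call. = FALSE)
  }
  if (anyNA(channel_g) || min(channel_g) < 0 || max(channel_g) > 255) {
    stop("green channel values must lie in [0, 255]", call. = FALSE)
  }
  clip8(alpha * channel_g)
}

#' Merge three channel grids into an RGB image
#'
#' @param channel_r,channel_g,channel_b Equal-shaped intensity grids in
#'   \[0, 255\]. Scalars are accepted for 1 x 1 images.
#' @return A height x width x 3 array; channel order is (R, G, B).
#' @export
merge_channels <- function(channel_r, channel_g, channel_b) {
  channel_r <- as.matrix(channel_r); channel_g <- as.matrix(channel_g)
  channel_b <- as.matrix(channel_b)
  if (!identical(dim(channel_r), dim(channel_g)) ||
      !identical(dim(channel_r), dim(channel_b))) {
    stop("channel grids must have identical shapes", call. = FALSE)
  }
  img <- array(c(channel_r, channel_g, channel_b), c(dim(channel_r), 3L))
  validate_rgb_image(img, "merged image")
  img
}

#' Zero the blue channel of an image
#'
#' Red and green are untouched; idempotent.
#'
#' @param img A height x width x 3 array in \[0, 255\].
#' @return The image with every blue value set to 0.
#' @export
suppress_blue <- function(img) {
  validate_rgb_image(img)
  img[, , 3] <- 0
  img
}

#' Render an image through a named colormap
#'
#' The processed green channel (the fluorescence proxy) is mapped pixelwise
#' through the 256-entry lookup table of the named colormap.
#'
#' @param img A height x width x 3 array in \[0, 255\].
#' @param colormap Colormap name; only `"HOT"` is defined.
#' @return An RGB image of the same spatial shape.
#' @export
apply_colormap <- function(img, colormap = "HOT") {
  validate_rgb_image(img)
  if (!is.character(colormap) || length(colormap) != 1L ||
      toupper(colormap) != "HOT") {
    stop("unknown colormap: ", colormap[1], " (supported: 'HOT')", call. = FALSE)
  }
  lut <- hot_colormap()
  idx <- clip8(img[, , 2, drop = TRUE]) + 1L      # intensity 0..255 -> row 1..256
  d <- dim(img)
  array(c(lut[idx, 1L], lut[idx, 2L], lut[idx, 3L]), d)
}

#' The full fluorescence-simulation transform
#'
#' Deterministic composition: split channels, amplify green by
#' `cfg$alpha` (rounded, clipped), re-merge as (R, G', B), then optionally
#' zero the blue channel and optionally render through the HOT colormap,
#' in that order. With `alpha = 1`, suppression off and no colormap the
#' transform is the identity.
#'
#' @param img A height x width x 3 array in \[0, 255\].
#' @param cfg A [fluorescence_config()].
#' @return The transformed image, same spatial shape as the input.
#' @export
fluorescence_simulate <- function(img, cfg = fluorescence_config()) {
  if (!inherits(cfg, "fluorescence_config")) {
    stop("`cfg` must be a fluorescence_config()", call. = FALSE)
  }
  ch <- split_channels(img)
  out <- merge_channels(ch$R, enhance_green(ch$G, cfg$alpha), ch$B)
  if (cfg$suppress_blue) out <- suppress_blue(out)
  if (cfg$colormap != "none") out <- apply_colormap(out, cfg$colormap)
  validate_rgb_image(out, "fluorescence output")
  out
}
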