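# Grad-CAM saliency over the frozen backbones' final convolutional feature
# maps. Because the classification head consumes globally averaged features,
# the spatial mean of the class-score gradient over a feature map equals the
# head's gradient with respect to the pooled feature divided by the number
# of spatial positions; the class-activation map is the ReLU of the
# channel-weighted sum of activations, min-max normalized and upsampled.

# gradient of one class logit with respect to both pooled feature vectors
pooled_gradients <- function(model, a, b, target_idx) {
  fw <- head_forward(model, a, b, training = FALSE)
  dlogits <- matrix(0, nrow(fw$logits), ncol(fw$logits))
  dlogits[, target_idx] <- 1
  bw <- head_backward(model, fw$cache, dlogits, training = FALSE)
  list(d_a = bw$d_a, d_b = bw$d_b, probs = fw$probs)
}

resolve_target <- function(model, target) {
  k <- model$num_classes
  if (is.numeric(target)) {
    idx <- as.integer(target)
    if (idx < 1L || idx > k) stop("class index out of range 1..", k,
                                  call. = FALSE)
    return(idx)
  }
  lv <- model$levels
  if (is.null(lv)) lv <- class_labels()[seq_len(k)]
  idx <- match(target, lv)
  if (is.na(idx)) stop("unknown target class: ", target, call. = FALSE)
  idx
}

cam_from_map <- function(fmap, d_pooled) {
  d <- dim(fmap)                       # h x w x C
  n_pos <- d[1] * d[2]
  alpha <- as.numeric(d_pooled) / n_pos
  raw <- matrix(matrix(fmap, ncol = d[3]) %*% alpha, d[1], d[2])
  raw <- pmax(raw, 0)
  m <- max(raw)
  if (m > 0) raw / m else raw
}

upsample_map <- function(map, height, width) {
  e <- EBImage::resize(EBImage::Image(t(map)), w = width, h = height)
  out <- t(EBImage::imageData(e))
  out <- pmin(pmax(out, 0), 1)
  m <- max(out)
  if (m > 0) out / m else out
}

#' Grad-CAM class-activation heatmap
#'
#' Computes the Grad-CAM map of a target class over the final convolutional
#' feature maps of the frozen backbones: channel weights are the spatial
#' means of the class-logit gradient with respect to the feature map, the
#' raw map is the ReLU of the weighted channel sum, and the result is
#' min-max normalized and bilinearly upsampled to the input size. `source`
#' selects the MobileNetV2-style map, the EfficientNetB0-style map, or their
#' average (`"combined"`, default).
#'
#' @param model A trained [build_fusion_model()].
#' @param backbones List of two [build_backbone()] objects (same order used
#'   in training).
#' @param img A height x width x 3 image in \[0, 255\] (already
#'   preprocessed/resized as in training).
#' @param target Class label name or 1-based class index.
#' @param source `"combined"`, `"backbone_a"` or `"backbone_b"`.
#' @return A height x width matrix of class `heatmap` with values in
#'   \[0, 1\] (max 1 unless the raw map is identically zero) and attributes
#'   `target` and `source`.
#' @export
gradcam <- function(model, backbones, img, target,
                    source = c("combined", "backbone_a", "backbone_b")) {
  source <- match.arg(source)
  validate_rgb_image(img)
  target_idx <- resolve_target(model, target)
  fa <- extract(backbones[[1]], img)
  fb <- extract(backbones[[2]], img)
  a <- gap(fa); b <- gap(fb)
  gr <- pooled_gradients(model, a, b, target_idx)
  h <- dim(img)[1]; w <- dim(img)[2]
  map_a <- cam_from_map(array(fa[1, , , ], dim(fa)[2:4]), gr$d_a)
  map_b <- cam_from_map(array(fb[1, , , ], dim(fb)[2:4]), gr$d_b)
  map <- switch(source,
                backbone_a = upsample_map(map_a, h, w),
                backbone_b = upsample_map(map_b, h, w),
                combined = {
                  m <- (upsample_map(map_a, h, w) +
                          upsample_map(map_b, h, w)) / 2
                  mx <- max(m)
                  if (mx > 0) m / mx else m
                })
  structure(map, class = c("heatmap", "matrix"),
            target = target, source = source)
}

#' Overlay a heatmap on an image
#'
#' Alpha-blends the HOT-colormapped heatmap over the image:
#' `out = (1 - opacity) * img + opacity * colormap(heatmap)`.
#'
#' @param img A height x width x 3 image in \[0, 255\].
#' @param heatmap A matrix in \[0, 1\] with the same spatial size (e.g. from
#'   [gradcam()]).
#' @param opacity Blend weight in \[0, 1\]; 0 returns the image, 1 the pure
#'   colormapped heatmap.
#' @return The blended RGB image.
#' @export
overlay <- function(img, heatmap, opacity = 0.5) {
  validate_rgb_image(img)
  if (!is.numeric(opacity) || length(opacity) != 1L || is.na(opacity) ||
      opacity < 0 || opacity > 1) {
    stop("`opacity` must be a single number in [0, 1]", call. = FALSE)
  }
  hm <- unclass(heatmap)
  if (!identical(dim(hm), dim(img)[1:2])) {
    stop("heatmap and image spatial sizes differ", call. = FALSE)
  }
  lut <- hot_colormap()
  idx <- clip8(hm * 255) + 1L
  cmap <- array(c(lut[idx, 1L], lut[idx, 2L], lut[idx, 3L]), dim(img))
  clip8((1 - opacity) * img + opacity * cmap)
}
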