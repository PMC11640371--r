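# Frozen convolutional feature extractors. Two families are provided, each
# built from its characteristic block: inverted residual blocks with linear
# bottlenecks (MobileNetV2 style) and MBConv blocks with squeeze-and-
# excitation gating (EfficientNetB0 style). The `tiny` scale is a 3-stage
# reduction of each family, self-contained and fast enough for CPU test
# runs; `full` builds the family's deeper stack but, with no weight zoo
# bundled, warns and falls back to seeded random initialization.

he_init <- function(kh, kw, cin, cout) {
  array(stats::rnorm(kh * kw * cin * cout, 0, sqrt(2 / (kh * kw * cin))),
        c(kh, kw, cin, cout))
}

new_bn <- function(c_out, eps = 1e-3) {
  list(gamma = rep(1, c_out), beta = rep(0, c_out),
       mean = rep(0, c_out), var = rep(1, c_out), eps = eps)
}

make_conv <- function(kh, kw, cin, cout, stride = 1L, act = "relu6",
                      bn = TRUE) {
  list(type = "conv", w = he_init(kh, kw, cin, cout), b = rep(0, cout),
       stride = stride, bn = if (bn) new_bn(cout) else NULL, act = act)
}

make_dw <- function(k, ch, stride = 1L, act = "relu6") {
  list(w = array(stats::rnorm(k * k * ch, 0, sqrt(2 / (k * k))), c(k, k, ch)),
       b = rep(0, ch), stride = stride, bn = new_bn(ch), act = act)
}

make_se <- function(ch, reduction = 4L) {
  mid <- max(1L, ch %/% reduction)
  list(w1 = matrix(stats::rnorm(ch * mid, 0, sqrt(2 / ch)), ch, mid),
       b1 = rep(0, mid),
       w2 = matrix(stats::rnorm(mid * ch, 0, sqrt(1 / mid)), mid, ch),
       b2 = rep(0, ch))
}

# Inverted-residual / MBConv block. `expand_ratio = 1` skips the expansion
# convolution; `se` adds squeeze-and-excitation gating after the depthwise
# stage; the additive skip is used when stride = 1 and cin = cout.
make_block <- function(cin, cout, stride = 1L, expand_ratio = 4L,
                       act = "relu6", se = FALSE) {
  cmid <- cin * expand_ratio
  list(
    type = "block", stride = stride, use_skip = (stride == 1L && cin == cout),
    expand = if (expand_ratio > 1L)
      list(w = he_init(1L, 1L, cin, cmid), b = rep(0, cmid),
           bn = new_bn(cmid), act = act) else NULL,
    dw = make_dw(3L, cmid, stride, act),
    se = if (se) make_se(cmid) else NULL,
    project = list(w = he_init(1L, 1L, cmid, cout), b = rep(0, cout),
                   bn = new_bn(cout))
  )
}

backbone_families <- c("mobilenet_v2_like", "efficientnet_b0_like")

#' Build a frozen convolutional feature extractor
#'
#' @param family `"mobilenet_v2_like"` (inverted residual blocks, ReLU6) or
#'   `"efficientnet_b0_like"` (MBConv blocks with squeeze-and-excitation,
#'   swish).
#' @param scale `"tiny"` (3-stage reduced network, the test-suite default) or
#'   `"full"` (the family's deeper stack). No pretrained weight zoo is
#'   bundled, so `"full"` emits an explicit warning and initializes randomly
#'   from `seed`.
#' @param seed Integer seed for weight initialization.
#' @param input_norm Input normalization applied before extraction:
#'   `"zscore"` (default) standardizes each image per channel, removing
#'   global illumination and color-balance variation; `"unit"` scales 8-bit
#'   intensities to \[0, 1\].
#' @return A list of class `backbone` with fields `family`, `scale`,
#'   `frozen` (always `TRUE`), `seed`, `input_norm`, `output_channels` and
#'   the layer stack.
#' @export
build_backbone <- function(family = backbone_families,
                           scale = c("tiny", "full"), seed = 0,
                           input_norm = c("zscore", "unit")) {
  family <- match.arg(family)
  scale <- match.arg(scale)
  input_norm <- match.arg(input_norm)
  act <- if (family == "mobilenet_v2_like") "relu6" else "swish"
  se <- family == "efficientnet_b0_like"
  layers <- withr::with_seed(seed, {
    if (scale == "tiny") {
      out_w <- if (family == "mobilenet_v2_like") 48L else 56L
      list(make_conv(3L, 3L, 3L, 12L, 2L, act),
           make_block(12L, 24L, 2L, 4L, act, se),
           make_block(24L, 24L, 1L, 4L, act, se),
           make_block(24L, out_w, 2L, 4L, act, se))
    } else {
      warning("no pretrained weights are bundled for scale = 'full' and no ",
              "download source is configured; using seeded random ",
              "initialization", call. = FALSE)
      widths <- if (family == "mobilenet_v2_like")
        c(16L, 24L, 32L, 64L, 96L, 160L, 320L) else
        c(16L, 24L, 40L, 80L, 112L, 192L, 320L)
      strides <- c(1L, 2L, 2L, 2L, 1L, 2L, 1L)
      expand <- c(1L, rep(6L, 6L))
      blocks <- list(make_conv(3L, 3L, 3L, 32L, 2L, act))
      cin <- 32L
      for (i in seq_along(widths)) {
        blocks[[length(blocks) + 1L]] <-
          make_block(cin, widths[i], strides[i], expand[i], act, se)
        cin <- widths[i]
      }
      blocks[[length(blocks) + 1L]] <- make_conv(1L, 1L, cin, 1280L, 1L, act)
      blocks
    }
  })
  last <- layers[[length(layers)]]
  out_ch <- if (last$type == "conv") dim(last$w)[4] else dim(last$project$w)[4]
  structure(list(family = family, scale = scale, frozen = TRUE, seed = seed,
                 input_norm = input_norm, output_channels = out_ch,
                 layers = layers),
            class = "backbone")
}

se_gate <- function(x, se) {
  z <- gap(x)
  g <- sigmoid(drop(relu(z %*% se$w1 + se$b1) %*% se$w2) + se$b2)
  d <- dim(x)
  array(sweep(matrix(x, ncol = d[3]), 2L, g, "*"), d)
}

run_conv_layer <- function(x, ly) {
  y <- conv2d(x, ly$w, ly$b, ly$stride)
  if (!is.null(ly$bn)) y <- bn_infer_map(y, ly$bn)
  apply_activation(y, ly$act)
}

run_block <- function(x, blk) {
  y <- x
  if (!is.null(blk$expand)) {
    y <- conv2d(y, blk$expand$w, blk$expand$b, 1L)
    y <- bn_infer_map(y, blk$expand$bn)
    y <- apply_activation(y, blk$expand$act)
  }
  y <- depthwise_conv2d(y, blk$dw$w, blk$dw$b, blk$dw$stride)
  y <- bn_infer_map(y, blk$dw$bn)
  y <- apply_activation(y, blk$dw$act)
  if (!is.null(blk$se)) y <- se_gate(y, blk$se)
  y <- conv2d(y, blk$project$w, blk$project$b, 1L)
  y <- bn_infer_map(y, blk$project$bn)      # linear bottleneck: no activation
  if (blk$use_skip) y <- y + x
  y
}

backbone_forward_one <- function(backbone, x) {
  for (ly in backbone$layers) {
    x <- if (ly$type == "conv") run_conv_layer(x, ly) else run_block(x, ly)
  }
  x
}

normalize_input <- function(img, input_norm) {
  x <- img / 255
  if (input_norm == "zscore") {
    for (cc in 1:3) {
      v <- x[, , cc]
      s <- stats::sd(v)
      x[, , cc] <- (v - mean(v)) / if (s > 0) s else 1
    }
  }
  x
}

as_image_batch <- function(batch) {
  if (is.list(batch)) return(batch)
  d <- dim(batch)
  if (length(d) == 3L) return(list(batch))
  if (length(d) == 4L) {
    return(lapply(seq_len(d[1]), function(i) array(batch[i, , , ], d[2:4])))
  }
  stop("`batch` must be an image, a list of images, or an N x H x W x 3 array",
       call. = FALSE)
}

#' Extract final-stage convolutional features
#'
#' Runs a frozen backbone forward over a batch of images and returns the
#' activations of the last convolutional stage (the Grad-CAM target layer).
#' No parameters are ever updated.
#'
#' @param backbone A [build_backbone()] object.
#' @param batch A single height x width x 3 image in \[0, 255\], a list of
#'   such images (equal sizes), or an N x H x W x 3 array.
#' @return An N x H' x W' x C feature-map array, where C equals
#'   `backbone$output_channels`.
#' @export
extract <- function(backbone, batch) {
  stopifnot(inherits(backbone, "backbone"))
  imgs <- as_image_batch(batch)
  lapply(imgs, validate_rgb_image)
  fm1 <- backbone_forward_one(backbone,
                              normalize_input(imgs[[1]], backbone$input_norm))
  d <- dim(fm1)
  out <- array(0, c(length(imgs), d))
  out[1, , , ] <- fm1
  if (length(imgs) > 1L) {
    for (i in 2:length(imgs)) {
      fm <- backbone_forward_one(backbone,
                                 normalize_input(imgs[[i]], backbone$input_norm))
      if (!identical(dim(fm), d)) {
        stop("images in a batch must share spatial dimensions", call. = FALSE)
      }
      out[i, , , ] <- fm
    }
  }
  out
}

#' Pooled features for a batch
#'
#' Convenience composition of [extract()] and [gap()].
#'
#' @inheritParams extract
#' @return An N x C matrix of globally averaged features.
#' @export
pooled_features <- function(backbone, batch) {
  gap(extract(backbone, batch))
}

# ---- parameter bookkeeping -------------------------------------------------

# flatten every numeric parameter array of a backbone (or head) into a named
# list, in a fixed traversal order
collect_params <- function(x, prefix = "") {
  out <- list()
  if (is.numeric(x)) {
    out[[prefix]] <- x
  } else if (is.list(x)) {
    nm <- names(x)
    for (i in seq_along(x)) {
      if (identical(nm[i], "eps") || identical(nm[i], "stride")) next
      key <- if (is.null(nm) || nm[i] == "") as.character(i) else nm[i]
      out <- c(out, collect_params(x[[i]], paste0(prefix, "/", key)))
    }
  }
  out
}

#' Checksum of all backbone parameters
#'
#' A deterministic numeric signature (count, sum, sum of squares, and an
#' order-sensitive weighted sum) over every parameter, used to assert the
#' freeze contract: the checksum is bit-identical before and after any
#' training step.
#'
#' @param backbone A [build_backbone()] object (or any nested parameter
#'   structure).
#' @return A named numeric vector of length 4.
#' @export
backbone_checksum <- function(backbone) {
  x <- unlist(collect_params(if (inherits(backbone, "backbone"))
    backbone$layers else backbone), use.names = FALSE)
  c(count = length(x), sum = sum(x), sumsq = sum(x^2),
    dot = sum(x * seq_along(x)))
}

#' Save / load a backbone checkpoint
#'
#' The checkpoint is a single portable file: a JSON object with a header
#' (family, scale, seed, input normalization, checksum) and every parameter
#' serialized losslessly as base64-encoded IEEE doubles.
#'
#' @param backbone A [build_backbone()] object.
#' @param path Checkpoint file path.
#' @return `save_backbone()` returns `path` invisibly; `load_backbone()`
#'   returns the restored backbone (bit-identical parameters).
#' @export
save_backbone <- function(backbone, path) {
  stopifnot(inherits(backbone, "backbone"))
  pars <- collect_params(backbone$layers)
  payload <- lapply(pars, function(p) {
    list(dim = if (is.null(dim(p))) length(p) else dim(p),
         data = jsonlite::base64_enc(writeBin(as.double(p), raw(),
                                              size = 8L, endian = "little")))
  })
  obj <- list(header = list(format = "fundusfusion-backbone-1",
                            family = backbone$family, scale = backbone$scale,
                            seed = backbone$seed,
                            input_norm = backbone$input_norm,
                            checksum = unname(backbone_checksum(backbone))),
              params = payload)
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}

#' @rdname save_backbone
#' @export
load_backbone <- function(path) {
  obj <- jsonlite::fromJSON(readLines(path, warn = FALSE),
                            simplifyVector = TRUE)
  hd <- obj$header
  bb <- suppressWarnings(
    build_backbone(hd$family, hd$scale, as.integer(hd$seed), hd$input_norm))
  pars <- lapply(obj$params, function(p) {
    v <- readBin(jsonlite::base64_dec(p$data), what = "double",
                 n = prod(unlist(p$dim)), size = 8L, endian = "little")
    if (length(p$dim) > 1L) dim(v) <- unlist(p$dim)
    v
  })
  bb$layers <- restore_params(bb$layers, pars, "")
  chk <- backbone_checksum(bb)
  if (!isTRUE(all.equal(unname(chk), unlist(hd$checksum),
                        check.attributes = FALSE))) {
    stop("checkpoint checksum mismatch: file is corrupt or truncated",
         call. = FALSE)
  }
  bb
}

# walk the same traversal as collect_params, writing stored values back
restore_params <- function(x, pars, prefix) {
  if (is.numeric(x)) {
    stored <- pars[[prefix]]
    if (is.null(stored)) stop("missing parameter in checkpoint: ", prefix)
    if (!is.null(dim(x))) dim(stored) <- dim(x)
    return(stored)
  }
  if (is.list(x)) {
    nm <- names(x)
    for (i in seq_along(x)) {
      if (is.null(x[[i]])) next
      if (identical(nm[i], "eps") || identical(nm[i], "stride")) next
      key <- if (is.null(nm) || nm[i] == "") as.character(i) else nm[i]
      x[i] <- list(restore_params(x[[i]], pars, paste0(prefix, "/", key)))
    }
  }
  x
}
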