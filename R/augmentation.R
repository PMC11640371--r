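# AutoAugment-style training-set augmentation and class balancing. A policy
# is an ordered set of sub-policies, each a short list of operations with an
# application probability and a magnitude level in 0..9 that maps onto a
# bounded geometric or photometric range. One randomly chosen sub-policy is
# applied per image. Balancing oversamples minority classes with augmented
# copies until every training class matches the largest one; the test split
# is never touched.

augment_ops <- c("rotate", "translate_x", "translate_y", "shear_x",
                 "shear_y", "flip_horizontal", "brightness", "contrast",
                 "color", "sharpness", "cutout", "crop_resize")

# magnitude level 0..9 -> fraction of the op's maximum range
mag_frac <- function(level) {
  stopifnot(level >= 0, level <= 9)
  level / 9
}

aug_op <- function(name, prob, magnitude) {
  if (!(name %in% augment_ops)) {
    stop("unknown augmentation operation: ", name, call. = FALSE)
  }
  if (prob < 0 || prob > 1) stop("probability must be in [0, 1]",
                                 call. = FALSE)
  if (magnitude < 0 || magnitude > 9) stop("magnitude level must be in 0..9",
                                           call. = FALSE)
  list(name = name, prob = prob, magnitude = magnitude)
}

#' Build an augmentation policy
#'
#' With `config = NULL` the default policy is returned: always-considered
#' base operations (horizontal flip with probability 0.5) plus five fixed
#' sub-policies — rotate (<= 15 degrees), translate (<= 10%), shear
#' (<= 8 degrees), brightness/contrast (within +/- 20%), and cutout
#' (<= 10% of the image area). An empty `config` (`list()`) yields the
#' identity augmenter.
#'
#' @param config `NULL` for the default; otherwise a list with optional
#'   elements `base_ops` and `sub_policies`, each a list of
#'   `(name, prob, magnitude)` triples drawn from the operation vocabulary:
#'   rotate, translate_x, translate_y, shear_x, shear_y, flip_horizontal,
#'   brightness, contrast, color, sharpness, cutout, crop_resize.
#' @return A list of class `augment_policy`.
#' @export
build_policy <- function(config = NULL) {
  if (is.null(config)) {
    config <- list(
      base_ops = list(list("flip_horizontal", 0.5, 0)),
      sub_policies = list(
        list(list("rotate", 0.7, 9)),
        list(list("translate_x", 0.6, 9), list("translate_y", 0.6, 9)),
        list(list("shear_x", 0.5, 9), list("shear_y", 0.5, 9)),
        list(list("brightness", 0.6, 9), list("contrast", 0.6, 9)),
        list(list("cutout", 0.5, 9))
      )
    )
  }
  norm_ops <- function(ops) lapply(ops, function(o) {
    if (is.list(o) && !is.null(o$name)) aug_op(o$name, o$prob, o$magnitude)
    else aug_op(o[[1]], as.numeric(o[[2]]), as.numeric(o[[3]]))
  })
  structure(list(base_ops = norm_ops(config$base_ops %||% list()),
                 sub_policies = lapply(config$sub_policies %||% list(),
                                       norm_ops)),
            class = "augment_policy")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- individual operations -------------------------------------------------

apply_geom <- function(img, fn) {
  from_ebimage(fn(to_ebimage(img)))
}

op_rotate <- function(img, frac, direction) {
  ang <- direction * frac * 15
  d <- dim(img)
  apply_geom(img, function(e)
    EBImage::rotate(e, ang, output.dim = c(d[2], d[1]), bg.col = "black"))
}

op_translate <- function(img, frac, direction, axis) {
  d <- dim(img)
  shift <- direction * frac * 0.10 * if (axis == "x") d[2] else d[1]
  v <- if (axis == "x") c(shift, 0) else c(0, shift)
  apply_geom(img, function(e) EBImage::translate(e, v, bg.col = "black"))
}

op_shear <- function(img, frac, direction, axis) {
  sh <- direction * frac * tan(8 * pi / 180)
  m <- if (axis == "x") matrix(c(1, sh, 0, 0, 1, 0), 3L, 2L) else
    matrix(c(1, 0, 0, sh, 1, 0), 3L, 2L)
  d <- dim(img)
  apply_geom(img, function(e)
    EBImage::affine(e, m, output.dim = c(d[2], d[1]), bg.col = "black"))
}

op_flip_h <- function(img) {
  img[, rev(seq_len(dim(img)[2])), , drop = FALSE]
}

op_brightness <- function(img, frac, direction) {
  clip8(img + direction * frac * 0.20 * 255)
}

op_contrast <- function(img, frac, direction) {
  f <- 1 + direction * frac * 0.20
  m <- mean(img)
  clip8((img - m) * f + m)
}

op_color <- function(img, frac, direction) {
  # saturation: blend toward/away from the luminance image
  f <- 1 + direction * frac * 0.20
  lum <- 0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
  gray <- array(lum, dim(img))
  clip8(gray + f * (img - gray))
}

op_sharpness <- function(img, frac, direction) {
  f <- direction * frac * 0.5
  blur <- from_ebimage(EBImage::gblur(to_ebimage(img), sigma = 1))
  clip8(img + f * (img - blur))
}

op_cutout <- function(img, frac) {
  d <- dim(img)
  side <- round(sqrt(frac * 0.10) * min(d[1], d[2]))
  if (side < 1) return(img)
  y0 <- sample.int(d[1] - side + 1L, 1L)
  x0 <- sample.int(d[2] - side + 1L, 1L)
  img[y0:(y0 + side - 1L), x0:(x0 + side - 1L), ] <- 0
  img
}

op_crop_resize <- function(img, frac) {
  d <- dim(img)
  keep <- 1 - frac * 0.20
  ch <- max(2L, round(keep * d[1])); cw <- max(2L, round(keep * d[2]))
  y0 <- sample.int(d[1] - ch + 1L, 1L)
  x0 <- sample.int(d[2] - cw + 1L, 1L)
  crop <- img[y0:(y0 + ch - 1L), x0:(x0 + cw - 1L), , drop = FALSE]
  resize_image(crop, d[2], d[1])
}

apply_op <- function(img, op) {
  frac <- mag_frac(op$magnitude)
  dir <- sample(c(-1, 1), 1L)
  switch(op$name,
         rotate = op_rotate(img, frac, dir),
         translate_x = op_translate(img, frac, dir, "x"),
         translate_y = op_translate(img, frac, dir, "y"),
         shear_x = op_shear(img, frac, dir, "x"),
         shear_y = op_shear(img, frac, dir, "y"),
         flip_horizontal = op_flip_h(img),
         brightness = op_brightness(img, frac, dir),
         contrast = op_contrast(img, frac, dir),
         color = op_color(img, frac, dir),
         sharpness = op_sharpness(img, frac, dir),
         cutout = op_cutout(img, frac),
         crop_resize = op_crop_resize(img, frac))
}

#' Augment one image
#'
#' Applies the policy's base operations (each with its probability), then
#' one uniformly chosen sub-policy whose operations fire independently with
#' their probabilities. Deterministic given `rng_seed`; output shape always
#' equals input shape, and geometric fills are black (fundus fields are
#' black-bordered).
#'
#' @param img A height x width x 3 image in \[0, 255\].
#' @param policy An [build_policy()] object.
#' @param rng_seed Integer seed for this call.
#' @return The augmented image.
#' @export
augment_image <- function(img, policy, rng_seed) {
  stopifnot(inherits(policy, "augment_policy"))
  validate_rgb_image(img)
  withr::with_seed(rng_seed, {
    for (op in policy$base_ops) {
      if (stats::runif(1) < op$prob) img <- apply_op(img, op)
    }
    if (length(policy$sub_policies) > 0) {
      sp <- policy$sub_policies[[sample.int(length(policy$sub_policies), 1L)]]
      for (op in sp) {
        if (stats::runif(1) < op$prob) img <- apply_op(img, op)
      }
    }
  })
  validate_rgb_image(img, "augmented image")
  img
}

#' Balance the training split by augmentation oversampling
#'
#' Every training class is brought up to the size of the largest training
#' class by adding augmented copies of seeded-randomly drawn originals;
#' no original is ever removed and the test split is returned bit-identical.
#' Augmented files are written as PNG under `out_dir` in class
#' subdirectories.
#'
#' @param manifest Dataset manifest (columns `path`, `label`, `split`,
#'   `source`).
#' @param policy An [build_policy()] object.
#' @param rng_seed Integer seed.
#' @param out_dir Directory for the augmented images; defaults to
#'   `<manifest root>/augmented`.
#' @return The balanced manifest (original rows first, augmented rows
#'   appended with `source = "augmented"`).
#' @export
balance_training_set <- function(manifest, policy, rng_seed,
                                 out_dir = NULL) {
  stopifnot(inherits(policy, "augment_policy"),
            all(c("path", "label", "split") %in% names(manifest)))
  if (is.null(out_dir)) {
    root <- attr(manifest, "root") %||% dirname(dirname(manifest$path[1]))
    out_dir <- file.path(root, "augmented")
  }
  tr <- manifest[manifest$split == "train", , drop = FALSE]
  counts <- table(factor(tr$label, levels = sort(unique(manifest$label))))
  if (any(counts == 0)) {
    stop("empty training class: ",
         paste(names(counts)[counts == 0], collapse = ", "), call. = FALSE)
  }
  target <- max(counts)
  new_rows <- list()
  seeds <- withr::with_seed(rng_seed,
                            sample.int(.Machine$integer.max - 1L,
                                       sum(target - counts) + length(counts)))
  si <- 0L
  for (lab in names(counts)) {
    deficit <- target - counts[[lab]]
    if (deficit == 0L) next
    src <- tr[tr$label == lab, , drop = FALSE]
    pick <- withr::with_seed(rng_seed + match(lab, sort(names(counts))),
                             sample.int(nrow(src), deficit, replace = TRUE))
    dir.create(file.path(out_dir, lab), recursive = TRUE,
               showWarnings = FALSE)
    for (i in seq_len(deficit)) {
      si <- si + 1L
      img <- read_image(src$path[pick[i]])
      aug <- augment_image(img, policy, seeds[si])
      p <- file.path(out_dir, lab, sprintf("aug_%s_%04d.png", lab, i))
      write_image(aug, p)
      new_rows[[length(new_rows) + 1L]] <- data.frame(
        path = p, label = lab, split = "train", source = "augmented",
        stringsAsFactors = FALSE)
    }
  }
  extra <- if (length(new_rows) > 0) do.call(rbind, new_rows) else NULL
  keep <- names(manifest)[names(manifest) %in%
                            c("path", "label", "split", "source")]
  out <- rbind(manifest[, keep, drop = FALSE],
               if (!is.null(extra)) extra[, keep, drop = FALSE])
  rownames(out) <- NULL
  attr(out, "root") <- attr(manifest, "root")
  out
}
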