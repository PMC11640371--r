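# Seeded synthetic fundus-image generator. Five visually separable classes
# are rendered with simple parametric shapes (circular retinal field, optic
# disc and cup, random-walk vessel tree, class-specific lesions). The point
# is class-discriminative structure for pipeline testing, not photorealism.

#' The five admissible class labels
#' @export
class_labels <- function() {
  c("normal", "diabetic_retinopathy", "hypertensive_retinopathy",
    "glaucoma", "contrast")
}

#' Parameters for the synthetic fundus generator
#'
#' Defaults emulate the acquisition setting the pipeline was designed around:
#' raw frames of 1125 x 1264 pixels (width x height) that are later resized
#' to 700 x 600 for modelling.
#'
#' @param n_per_class Images per class (single value or named per-class vector).
#' @param raw_width,raw_height Raw frame size in pixels; both must be >= 64.
#' @param seed Master seed for dataset generation.
#' @param test_fraction Stratified held-out fraction, default 0.15.
#' @param dr_dots,dr_exudates Mean counts of diabetic-retinopathy dot
#'   hemorrhages and bright exudate blobs.
#' @param hr_patches Mean count of hypertensive cotton-wool patches.
#' @param hr_vessel_factor Vessel-width multiplier for hypertensive
#'   retinopathy (< 1 thins the arterioles).
#' @param cup_ratio_normal Cup/disc area ratio drawn for non-glaucomatous
#'   eyes.
#' @param cup_ratio_glaucoma Range of cup/disc area ratios for glaucoma
#'   (kept above the conventional 0.6 suspicion threshold).
#' @param haze_strength Blend weight toward mid-gray for the contrast class.
#' @param noise_sd Additive Gaussian pixel noise (8-bit units).
#' @return A list of class `generator_params`.
#' @export
generator_params <- function(n_per_class = 100,
                             raw_width = 1125, raw_height = 1264,
                             seed = 1, test_fraction = 0.15,
                             dr_dots = 14, dr_exudates = 6,
                             hr_patches = 4, hr_vessel_factor = 0.45,
                             cup_ratio_normal = 0.30,
                             cup_ratio_glaucoma = c(0.65, 0.80),
                             haze_strength = 0.45, contrast_blur = 0.008,
                             noise_sd = 3) {
  stopifnot(raw_width >= 64, raw_height >= 64, all(n_per_class >= 0),
            test_fraction >= 0, test_fraction < 1,
            haze_strength > 0, haze_strength < 1,
            all(cup_ratio_glaucoma > 0.6), cup_ratio_normal < 0.6)
  structure(as.list(environment()), class = "generator_params")
}

# ---- drawing primitives (operate on a list of three H x W matrices) -------

blank_canvas <- function(h, w, value = c(5, 5, 5)) {
  list(R = matrix(value[1], h, w), G = matrix(value[2], h, w),
       B = matrix(value[3], h, w))
}

# stamp a filled disk, optionally soft-edged, blending toward `col`
stamp_disk <- function(cv, cy, cx, r, col, opacity = 1, soft = 0) {
  h <- nrow(cv$R); w <- ncol(cv$R)
  y0 <- max(1L, floor(cy - r - 3 * soft)); y1 <- min(h, ceiling(cy + r + 3 * soft))
  x0 <- max(1L, floor(cx - r - 3 * soft)); x1 <- min(w, ceiling(cx + r + 3 * soft))
  if (y0 > y1 || x0 > x1) return(cv)
  yy <- matrix(y0:y1, y1 - y0 + 1L, x1 - x0 + 1L)
  xx <- matrix(x0:x1, y1 - y0 + 1L, x1 - x0 + 1L, byrow = TRUE)
  d <- sqrt((yy - cy)^2 + (xx - cx)^2)
  a <- if (soft > 0) opacity * pmin(1, pmax(0, (r - d) / soft + 1)) else
    opacity * (d <= r)
  for (ch in 1:3) {
    sub <- cv[[ch]][y0:y1, x0:x1]
    cv[[ch]][y0:y1, x0:x1] <- sub * (1 - a) + col[ch] * a
  }
  cv
}

# stamp a Gaussian blob of peak opacity `amp` and spread `sigma`
stamp_blob <- function(cv, cy, cx, sigma, col, amp = 0.8) {
  h <- nrow(cv$R); w <- ncol(cv$R)
  y0 <- max(1L, floor(cy - 3 * sigma)); y1 <- min(h, ceiling(cy + 3 * sigma))
  x0 <- max(1L, floor(cx - 3 * sigma)); x1 <- min(w, ceiling(cx + 3 * sigma))
  if (y0 > y1 || x0 > x1) return(cv)
  yy <- matrix(y0:y1, y1 - y0 + 1L, x1 - x0 + 1L)
  xx <- matrix(x0:x1, y1 - y0 + 1L, x1 - x0 + 1L, byrow = TRUE)
  a <- amp * exp(-((yy - cy)^2 + (xx - cx)^2) / (2 * sigma^2))
  for (ch in 1:3) {
    sub <- cv[[ch]][y0:y1, x0:x1]
    cv[[ch]][y0:y1, x0:x1] <- sub * (1 - a) + col[ch] * a
  }
  cv
}

# Compute the point set of one random-walk vessel (vectorized): positions,
# per-point radii (tapering toward the periphery), truncated at field exit.
vessel_points <- function(cy, cx, theta0, width, field_c, field_r,
                          curviness = 0.12) {
  step <- max(1, field_r / 120)
  n_steps <- ceiling(1.25 * field_r / step)
  theta <- theta0 + cumsum(stats::rnorm(n_steps, 0, curviness))
  y <- cy + cumsum(step * sin(theta))
  x <- cx + cumsum(step * cos(theta))
  inside <- (y - field_c[1])^2 + (x - field_c[2])^2 <= (0.97 * field_r)^2
  keep <- if (all(inside)) n_steps else which(!inside)[1] - 1L
  if (keep < 1L) return(NULL)
  i <- seq_len(keep)
  list(y = y[i], x = x[i], r = pmax(1, width * (1 - 0.5 * i / n_steps)))
}

# Stamp many hard-edged disks of one color in a single pass. For each offset
# (dy, dx) within the largest radius, all disks covering that offset are
# blended at once via vector indexing; this keeps the canvas update in-place.
stamp_disks_batch <- function(cv, y, x, r, col, opacity = 0.85) {
  h <- nrow(cv$R); w <- ncol(cv$R)
  rmax <- ceiling(max(r))
  R <- cv$R; G <- cv$G; B <- cv$B
  r2 <- r^2
  yi <- round(y); xi <- round(x)
  for (dy in -rmax:rmax) {
    for (dx in -rmax:rmax) {
      d2 <- dy^2 + dx^2
      sel <- d2 <= r2
      if (!any(sel)) next
      yy <- yi[sel] + dy; xx <- xi[sel] + dx
      ok <- yy >= 1 & yy <= h & xx >= 1 & xx <= w
      if (!any(ok)) next
      idx <- yy[ok] + (xx[ok] - 1) * h
      R[idx] <- R[idx] * (1 - opacity) + col[1] * opacity
      G[idx] <- G[idx] * (1 - opacity) + col[2] * opacity
      B[idx] <- B[idx] * (1 - opacity) + col[3] * opacity
    }
  }
  list(R = R, G = G, B = B)
}

# ---- per-class image synthesis --------------------------------------------

#' Generate one synthetic fundus image
#'
#' Deterministic given `(label, seed, params)`. Every image contains a
#' circular retinal field on a dark background, an optic disc with a central
#' cup, and a branching vessel tree; class-specific signatures are then
#' added: dot hemorrhages plus bright exudates (diabetic retinopathy),
#' thinned vessels plus cotton-wool patches (hypertensive retinopathy), an
#' enlarged cup with cup/disc area ratio above 0.6 (glaucoma), and a global
#' haze toward mid-gray (contrast). The drawn cup/disc area ratio is recorded
#' in the `meta` attribute.
#'
#' @param label One of [class_labels()].
#' @param seed Integer seed for this image.
#' @param params A [generator_params()].
#' @return An RGB image array of size `raw_height` x `raw_width` x 3 with a
#'   `meta` attribute (list with `label`, `seed`, `cup_disc_ratio`).
#' @export
generate_image <- function(label, seed, params = generator_params()) {
  if (!is.character(label) || length(label) != 1L || !(label %in% class_labels())) {
    stop("unknown class label: ", paste(label, collapse = ","),
         " (expected one of ", paste(class_labels(), collapse = ", "), ")",
         call. = FALSE)
  }
  h <- params$raw_height; w <- params$raw_width
  scale <- min(h, w)
  withr::with_seed(seed, {
    cv <- blank_canvas(h, w)
    field_c <- c(h / 2, w / 2)
    field_r <- 0.47 * scale
    # retinal field: warm base with a brighter center
    base_col <- c(178 + stats::runif(1, -12, 12), 88 + stats::runif(1, -8, 8),
                  32 + stats::runif(1, -6, 6))
    cv <- stamp_disk(cv, field_c[1], field_c[2], field_r, base_col,
                     soft = 0.02 * scale)
    cv <- stamp_blob(cv, field_c[1], field_c[2], 0.45 * field_r,
                     pmin(base_col * 1.25, 255), amp = 0.5)
    # optic disc (nasal offset) and cup
    disc_c <- c(field_c[1] + stats::runif(1, -0.06, 0.06) * field_r,
                field_c[2] + sample(c(-1, 1), 1) * 0.32 * field_r)
    disc_r <- 0.14 * field_r
    cup_ratio <- if (label == "glaucoma") {
      stats::runif(1, params$cup_ratio_glaucoma[1], params$cup_ratio_glaucoma[2])
    } else params$cup_ratio_normal
    if (label == "glaucoma") {
      # peripapillary atrophy: pale crescent ring around the disc, a
      # standard accompaniment of glaucomatous cupping
      cv <- stamp_disk(cv, disc_c[1], disc_c[2],
                       stats::runif(1, 1.6, 2.0) * disc_r, c(238, 192, 130),
                       opacity = 0.65, soft = 0.02 * scale)
    }
    # disc rim kept orange (green stays unsaturated under enhancement);
    # the cup is near-white and much brighter than the rim
    cv <- stamp_disk(cv, disc_c[1], disc_c[2], disc_r, c(222, 112, 60),
                     soft = 0.01 * scale)
    cv <- stamp_disk(cv, disc_c[1], disc_c[2], disc_r * sqrt(cup_ratio),
                     c(250, 228, 185), soft = 0.008 * scale)
    # vessel tree rooted at the disc
    vessel_w <- 0.008 * scale *
      if (label == "hypertensive_retinopathy") params$hr_vessel_factor else 1
    n_vessels <- 6L
    pts <- list()
    for (k in seq_len(n_vessels)) {
      theta <- 2 * pi * (k - 0.5) / n_vessels + stats::rnorm(1, 0, 0.25)
      pts[[length(pts) + 1L]] <-
        vessel_points(disc_c[1], disc_c[2], theta, vessel_w, field_c, field_r)
      # one side branch per trunk
      br <- 0.35 * field_r
      pts[[length(pts) + 1L]] <-
        vessel_points(disc_c[1] + br * sin(theta), disc_c[2] + br * cos(theta),
                      theta + sample(c(-1, 1), 1) * 0.6,
                      0.6 * vessel_w, field_c, field_r)
    }
    pts <- pts[!vapply(pts, is.null, logical(1))]
    if (length(pts) > 0) {
      cv <- stamp_disks_batch(cv,
                              unlist(lapply(pts, `[[`, "y")),
                              unlist(lapply(pts, `[[`, "x")),
                              unlist(lapply(pts, `[[`, "r")),
                              col = c(125, 32, 24))
    }
    # class signatures
    rand_in_field <- function(margin = 0.85) {
      repeat {
        y <- stats::runif(1, field_c[1] - margin * field_r, field_c[1] + margin * field_r)
        x <- stats::runif(1, field_c[2] - margin * field_r, field_c[2] + margin * field_r)
        if ((y - field_c[1])^2 + (x - field_c[2])^2 <= (margin * field_r)^2)
          return(c(y, x))
      }
    }
    if (label == "diabetic_retinopathy") {
      for (i in seq_len(stats::rpois(1, params$dr_dots) + 4L)) {
        p <- rand_in_field()
        cv <- stamp_disk(cv, p[1], p[2], stats::runif(1, 0.004, 0.010) * scale,
                         c(92, 12, 10), soft = 0.003 * scale)
      }
      for (i in seq_len(stats::rpois(1, params$dr_exudates) + 2L)) {
        p <- rand_in_field()
        cv <- stamp_blob(cv, p[1], p[2], stats::runif(1, 0.010, 0.022) * scale,
                         c(255, 242, 80), amp = 0.9)
      }
    } else if (label == "hypertensive_retinopathy") {
      for (i in seq_len(stats::rpois(1, params$hr_patches) + 2L)) {
        p <- rand_in_field()
        cv <- stamp_blob(cv, p[1], p[2], stats::runif(1, 0.02, 0.04) * scale,
                         c(198, 226, 210), amp = 0.6)
      }
    }
    img <- array(c(cv$R, cv$G, cv$B), c(h, w, 3L))
    img <- img + array(stats::rnorm(length(img), 0, params$noise_sd), dim(img))
    if (label == "contrast") {
      # media opacity: global haze toward mid-gray plus optical blur
      img <- (1 - params$haze_strength) * img + params$haze_strength * 160
      e <- EBImage::gblur(EBImage::Image(aperm(img, c(2L, 1L, 3L)) / 255,
                                         colormode = "Color"),
                          sigma = max(1, params$contrast_blur * scale))
      img <- aperm(EBImage::imageData(e), c(2L, 1L, 3L)) * 255
    }
    img <- clip8(img)
    attr(img, "meta") <- list(label = label, seed = seed,
                              cup_disc_ratio = cup_ratio,
                              disc_radius = disc_r,
                              cup_radius = disc_r * sqrt(cup_ratio))
    img
  })
}

#' Generate a labeled synthetic dataset on disk
#'
#' Writes PNG files in a class-per-subdirectory layout under `out_dir`,
#' assigns a seeded stratified train/test split, and writes the manifest as
#' `manifest.csv` in `out_dir`.
#'
#' @param params A [generator_params()].
#' @param out_dir Output directory (created if needed).
#' @return The manifest: a data frame with columns `path`, `label`, `split`,
#'   `source`, with the dataset root stored in the `"root"` attribute.
#' @export
generate_dataset <- function(params = generator_params(), out_dir) {
  stopifnot(!missing(out_dir))
  labels <- class_labels()
  n <- params$n_per_class
  if (length(n) == 1L) n <- stats::setNames(rep(n, 5L), labels)
  stopifnot(all(labels %in% names(n)))
  total <- sum(n[labels])
  seeds <- withr::with_seed(params$seed,
                            sample.int(.Machine$integer.max - 1L, total))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- vector("list", length(labels))
  k <- 0L
  for (lab in labels) {
    dir.create(file.path(out_dir, lab), showWarnings = FALSE)
    n_lab <- n[[lab]]
    if (n_lab == 0L) next
    paths <- file.path(out_dir, lab, sprintf("%s_%04d.png", lab, seq_len(n_lab)))
    for (i in seq_len(n_lab)) {
      img <- generate_image(lab, seeds[k + i], params)
      write_image(img, paths[i])
    }
    n_test <- round(params$test_fraction * n_lab)
    split <- rep("train", n_lab)
    if (n_test > 0) {
      test_idx <- withr::with_seed(params$seed + match(lab, labels),
                                   sample.int(n_lab, n_test))
      split[test_idx] <- "test"
    }
    rows[[match(lab, labels)]] <- data.frame(
      path = paths, label = lab, split = split, source = "synthetic",
      stringsAsFactors = FALSE)
    k <- k + n_lab
  }
  manifest <- do.call(rbind, rows)
  rownames(manifest) <- NULL
  attr(manifest, "root") <- out_dir
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  manifest
}

#' Per-source composition of the multi-source fundus corpus
#'
#' Returns, verbatim, the published per-source image counts of the
#' five-class fundus corpus this pipeline was designed around (eight source
#' collections; grand total 65,871 images). The printed table is internally
#' inconsistent: one source row prints a total of 4101 while its class cells
#' sum to 4911, so the grand total matches the sum of the printed row totals
#' but not the sum of the printed column totals. The table is reproduced
#' as printed and the inconsistency is flagged, not repaired.
#'
#' @return A list of class `dataset_composition` with elements `table`
#'   (data frame of per-source counts; `NA` marks classes a source does not
#'   contribute), `row_total_sum`, `column_sums`, `column_total_sum`,
#'   `inconsistent_rows` (source names whose printed total differs from the
#'   sum of their cells) and `consistent` (`FALSE` here).
#' @export
dataset_composition <- function() {
  tab <- data.frame(
    source = c("Eyepacs, Aptos, Messidor", "Eye disease dataset",
               "Eye disease classification", "Dataset for different eye diseases",
               "DiaRetDB1", "PAK-HR", "DR-Insight", "Imam-HR"),
    normal = c(23125, NA, 250, 1637, 100, 3000, 1000, 1130),
    diabetic_retinopathy = c(23125, NA, 250, NA, 100, NA, NA, NA),
    hypertensive_retinopathy = c(NA, NA, NA, NA, NA, 3000, 4000, 2040),
    glaucoma = c(NA, 50, 250, 1637, NA, NA, NA, NA),
    contrast = c(NA, 100, 250, 1637, NA, NA, NA, NA),
    total = c(46250, 150, 1000, 4101, 200, 6000, 5000, 3170),
    stringsAsFactors = FALSE
  )
  cell_sums <- rowSums(tab[, 2:6], na.rm = TRUE)
  inconsistent <- tab$source[cell_sums != tab$total]
  col_sums <- colSums(tab[, 2:6], na.rm = TRUE)
  structure(
    list(table = tab,
         row_total_sum = sum(tab$total),
         column_sums = col_sums,
         column_total_sum = sum(col_sums),
         inconsistent_rows = inconsistent,
         consistent = length(inconsistent) == 0L &&
           sum(tab$total) == sum(col_sums)),
    class = "dataset_composition"
  )
}

#' @export
print.dataset_composition <- function(x, ...) {
  print(x$table)
  cat(sprintf("\nSum of printed row totals: %d\n", x$row_total_sum))
  cat(sprintf("Sum of printed column sums: %d\n", x$column_total_sum))
  if (!x$consistent) {
    cat("NOTE: the printed table is internally inconsistent (rows: ",
        paste(x$inconsistent_rows, collapse = ", "),
        "); reproduced as printed, not repaired.\n", sep = "")
  }
  invisible(x)
}
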