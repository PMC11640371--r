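test_that("image generation is deterministic and respects the raw geometry", {
  p <- small_params()
  a <- generate_image("normal", 1, p)
  b <- generate_image("normal", 1, p)
  expect_identical(a, b)
  expect_equal(dim(a), c(p$raw_height, p$raw_width, 3L))
  for (lab in class_labels()) {
    img <- generate_image(lab, 7, p)
    expect_true(is_rgb_image(img))
  }
  expect_error(generate_image("macular_degeneration", 1, p), "unknown class")
})

test_that("glaucomatous eyes have cup/disc area ratio above 0.6", {
  p <- small_params()
  for (s in c(3, 7, 21)) {
    meta <- attr(generate_image("glaucoma", s, p), "meta")
    expect_gt(meta$cup_disc_ratio, 0.6)
    # shape-area oracle: the drawn circle areas must reproduce the ratio
    expect_equal((meta$cup_radius / meta$disc_radius)^2, meta$cup_disc_ratio,
                 tolerance = 1e-12)
  }
  meta_n <- attr(generate_image("normal", 3, p), "meta")
  expect_lt(meta_n$cup_disc_ratio, 0.6)
})

test_that("haze strictly lowers global intensity spread", {
  p <- small_params()
  nrm <- generate_image("normal", 3, p)
  con <- generate_image("contrast", 3, p)
  expect_lt(stats::sd(con), stats::sd(nrm))
})

test_that("dataset generation writes the manifest it promises", {
  ds <- test_dataset()
  man <- ds$manifest
  expect_equal(nrow(man), 30L)                      # 6 images x 5 classes
  expect_true(all(file.exists(man$path)))
  expect_equal(length(list.files(ds$dir, recursive = TRUE,
                                 pattern = "\\.png$")), 30L)
  expect_equal(sort(unique(man$label)), sort(class_labels()))
  # stratified split arithmetic: fraction 1/3 of 6 per class
  split_tab <- table(man$label, man$split)
  expect_true(all(split_tab[, "test"] == 2L))
  expect_true(all(split_tab[, "train"] == 4L))
  expect_true(file.exists(file.path(ds$dir, "manifest.csv")))
})

test_that("regeneration with the same seed is byte-identical", {
  p <- small_params(n_per_class = 2, seed = 5)
  d1 <- tempfile("ds1"); d2 <- tempfile("ds2")
  m1 <- generate_dataset(p, d1)
  m2 <- generate_dataset(p, d2)
  expect_identical(m1[c("label", "split")], m2[c("label", "split")])
  expect_identical(basename(m1$path), basename(m2$path))
  sums1 <- unname(tools::md5sum(m1$path))
  sums2 <- unname(tools::md5sum(m2$path))
  expect_identical(sums1, sums2)
})

test_that("split fraction arithmetic matches its definition", {
  p <- small_params(n_per_class = 20, seed = 2, test_fraction = 0.15)
  d <- tempfile("split")
  man <- generate_dataset(p, d)
  tab <- table(man$label, man$split)
  expect_true(all(tab[, "test"] == round(0.15 * 20)))
})

test_that("the packaged corpus composition reproduces the printed counts", {
  comp <- dataset_composition()
  expect_equal(comp$row_total_sum, 65871)
  expect_equal(unname(comp$column_sums[["normal"]]), 30242)
  expect_equal(unname(comp$column_sums[["hypertensive_retinopathy"]]), 9040)
  expect_equal(unname(comp$column_sums[["diabetic_retinopathy"]]), 23475)
  expect_equal(unname(comp$column_sums[["glaucoma"]]), 1937)
  expect_equal(unname(comp$column_sums[["contrast"]]), 1987)
  # the documented internal inconsistency is flagged, not repaired
  expect_false(comp$consistent)
  expect_equal(comp$inconsistent_rows, "Dataset for different eye diseases")
  row <- comp$table[comp$table$source == "Dataset for different eye diseases", ]
  expect_equal(row$total, 4101)                      # printed value kept
  expect_equal(sum(row[, 2:6], na.rm = TRUE), 4911)  # what the cells sum to
  expect_equal(comp$column_total_sum, 66681)
  expect_output(print(comp), "inconsistent")
})

test_that("classes separate above chance for a trivial channel-mean baseline", {
  p <- small_params(n_per_class = 10, seed = 31)
  d <- tempfile("base")
  man <- generate_dataset(p, d)
  feats <- t(vapply(man$path, function(pp) {
    img <- read_image(pp)
    c(mean(img[, , 1]), mean(img[, , 2]), mean(img[, , 3]))
  }, numeric(3)))
  centroids <- sapply(class_labels(),
                      function(l) colMeans(feats[man$label == l, ,
                                                 drop = FALSE]))
  pred <- class_labels()[apply(feats, 1, function(r)
    which.min(colSums((centroids - r)^2)))]
  expect_gt(mean(pred == man$label), 0.2)
})
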