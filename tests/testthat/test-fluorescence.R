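test_that("channel split and merge are mutually inverse", {
  px <- array(c(10, 100, 50), c(1, 1, 3))
  ch <- split_channels(px)
  expect_equal(ch$R, matrix(10, 1, 1)[1, 1])
  expect_equal(ch$G, 100)
  expect_equal(ch$B, 50)
  expect_equal(merge_channels(ch$R, ch$G, ch$B), px)

  zero <- array(0, c(2, 2, 3))
  chz <- split_channels(zero)
  expect_true(all(chz$R == 0) && all(chz$G == 0) && all(chz$B == 0))

  img <- seeded_image(6, 7, seed = 3)
  ch2 <- split_channels(img)
  expect_identical(merge_channels(ch2$R, ch2$G, ch2$B), img)

  expect_error(split_channels(array(0, c(2, 2, 2))), "3 channels")
  expect_error(merge_channels(matrix(0, 2, 2), matrix(0, 2, 3),
                              matrix(0, 2, 2)), "identical shapes")
})

test_that("green enhancement scales, rounds, and saturates at 255", {
  expect_equal(enhance_green(100, 2.0), 200)
  expect_equal(enhance_green(200, 2.0), 255)
  expect_equal(enhance_green(0, 7.3), 0)
  # round-half-away-from-zero after scaling
  expect_equal(enhance_green(1, 1.5), 2)
  expect_equal(enhance_green(3, 1.5), 5)
  g <- matrix(c(0, 10, 127, 128, 254, 255), 2, 3)
  expect_equal(enhance_green(g, 2), matrix(c(0, 20, 254, 255, 255, 255), 2, 3))
  expect_error(enhance_green(10, 0), "positive")
  expect_error(enhance_green(10, -1), "positive")
})

test_that("blue suppression zeroes exactly the blue channel and is idempotent", {
  px <- array(c(10, 200, 50), c(1, 1, 3))
  out <- suppress_blue(px)
  expect_equal(as.numeric(out), c(10, 200, 0))
  expect_identical(suppress_blue(out), out)
  img <- seeded_image(5, 6, seed = 9)
  out2 <- suppress_blue(img)
  expect_equal(max(out2[, , 3]), 0)
  expect_identical(out2[, , 1:2], img[, , 1:2])
})

test_that("HOT colormap maps the green channel through the fixed table", {
  lut <- hot_colormap()
  expect_equal(dim(lut), c(256L, 3L))
  expect_equal(unname(lut[1, ]), c(0, 0, 0))       # black endpoint
  expect_equal(unname(lut[256, ]), c(255, 255, 255))  # white endpoint

  img <- seeded_image(4, 5, seed = 2)
  out <- apply_colormap(img, "HOT")
  # per-pixel table-indexing oracle
  for (i in seq_len(4)) for (j in seq_len(5)) {
    expect_equal(unname(out[i, j, ]), unname(lut[img[i, j, 2] + 1, ]))
  }
  expect_error(apply_colormap(img, "viridis"), "unknown colormap")
})

test_that("full transform composes the steps with documented defaults", {
  cfg <- fluorescence_config()
  expect_equal(cfg$alpha, 2.0)
  expect_true(cfg$suppress_blue)
  expect_equal(cfg$colormap, "none")

  px <- array(c(10, 100, 50), c(1, 1, 3))
  expect_equal(as.numeric(fluorescence_simulate(px, cfg)), c(10, 200, 0))
  zero <- array(0, c(3, 4, 3))
  expect_identical(fluorescence_simulate(zero, cfg), zero)
})

test_that("transform invariants: range, red preservation, identity, determinism", {
  img <- seeded_image(7, 6, seed = 11)
  cfg <- fluorescence_config()
  out <- fluorescence_simulate(img, cfg)
  expect_true(min(out) >= 0 && max(out) <= 255)
  expect_identical(out[, , 1], img[, , 1])           # red bit-identical
  expect_identical(out, fluorescence_simulate(img, cfg))  # deterministic

  # with suppression off, blue is bit-identical
  out2 <- fluorescence_simulate(img, fluorescence_config(2, FALSE))
  expect_identical(out2[, , 3], img[, , 3])

  # alpha 1, suppression off, no colormap: identity
  expect_identical(fluorescence_simulate(img, fluorescence_config(1, FALSE)),
                   img)
})

test_that("applying the transform twice composes the green scaling", {
  img <- seeded_image(6, 6, seed = 5)
  cfg <- fluorescence_config(alpha = 2)
  twice <- fluorescence_simulate(fluorescence_simulate(img, cfg), cfg)
  expect_equal(max(twice[, , 3]), 0)
  expect_equal(twice[, , 2], pmin(4 * img[, , 2], 255))
  expect_identical(twice[, , 1], img[, , 1])
})

test_that("bit-exact golden: a fixed 2 x 2 frame under the default transform", {
  img <- array(0, c(2, 2, 3))
  img[, , 1] <- matrix(c(7, 80, 150, 255), 2, 2)
  img[, , 2] <- matrix(c(10, 100, 128, 200), 2, 2)
  img[, , 3] <- matrix(c(3, 60, 90, 255), 2, 2)
  out <- fluorescence_simulate(img, fluorescence_config())
  expect_identical(out[, , 1], img[, , 1])
  expect_equal(out[, , 2], matrix(c(20, 200, 255, 255), 2, 2))
  expect_equal(unique(as.numeric(out[, , 3])), 0)

  # HOT branch golden, computed from the table definition
  outh <- fluorescence_simulate(img, fluorescence_config(colormap = "HOT"))
  lut <- hot_colormap()
  gp <- pmin(2 * img[, , 2], 255)
  expect_equal(outh[, , 1], matrix(lut[gp + 1, 1], 2, 2))
  expect_equal(outh[, , 2], matrix(lut[gp + 1, 2], 2, 2))
  expect_equal(outh[, , 3], matrix(lut[gp + 1, 3], 2, 2))
})
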