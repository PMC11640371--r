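# Shared fixtures, built in code. Desk-scale generator settings keep the
# 1125:1264 raw aspect and the 7:6 resize aspect of the full-size pipeline.

small_params <- function(n_per_class = 4, seed = 1, raw_width = 128,
                         raw_height = 144, ...) {
  generator_params(n_per_class = n_per_class, seed = seed,
                   raw_width = raw_width, raw_height = raw_height, ...)
}

seeded_image <- function(h = 8, w = 9, seed = 1) {
  withr::with_seed(seed, {
    array(as.double(sample(0:255, h * w * 3, replace = TRUE)),
          c(h, w, 3))
  })
}

# tiny backbones are deterministic given seed; cache per session
.test_env <- new.env(parent = emptyenv())
test_backbones <- function() {
  if (is.null(.test_env$bb)) {
    .test_env$bb <- list(
      build_backbone("mobilenet_v2_like", "tiny", 0),
      build_backbone("efficientnet_b0_like", "tiny", 0)
    )
  }
  .test_env$bb
}

# a small on-disk dataset shared across tests that need files
test_dataset <- function() {
  if (is.null(.test_env$dataset)) {
    dir <- file.path(tempdir(), "ff-test-data")
    manifest <- generate_dataset(small_params(n_per_class = 6, seed = 42,
                                              test_fraction = 1 / 3), dir)
    .test_env$dataset <- list(dir = dir, manifest = manifest)
  }
  .test_env$dataset
}
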