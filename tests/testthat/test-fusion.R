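test_that("fusion operators combine pooled features as defined", {
  expect_equal(as.numeric(fuse(c(1, 2), c(3))), c(1, 2, 3))
  expect_equal(as.numeric(fuse(c(1, 2), c(3, 4), "sum")), c(4, 6))
  expect_equal(as.numeric(fuse(c(2, 3), c(4, 5), "product")), c(8, 15))
  expect_error(fuse(c(1, 2), c(3), "sum"), "equal widths")
  expect_error(fuse(matrix(0, 2, 3), matrix(0, 3, 3)), "batch sizes")
})

test_that("batch normalization matches its hand-evaluated definition", {
  bp <- batch_norm_params(1)
  out <- batch_norm(matrix(c(2, 4), 2, 1), bp, training = TRUE)
  # mu = 3, sigma2 = 1 (population), epsilon-perturbed unit outputs
  expect_equal(as.numeric(out$y), c(-1, 1) / sqrt(1 + bp$epsilon),
               tolerance = 1e-12)
  # running statistics moved toward the batch
  expect_equal(out$params$mean, 0.9 * 0 + 0.1 * 3)

  # gamma = 0 collapses the output to the constant beta
  bp2 <- batch_norm_params(2)
  bp2$gamma <- c(0, 0); bp2$beta <- c(5, -1)
  out2 <- batch_norm(matrix(stats::rnorm(10), 5, 2), bp2, training = TRUE)
  expect_equal(out2$y, matrix(rep(c(5, -1), each = 5), 5, 2))

  expect_error(batch_norm(matrix(1, 1, 1), batch_norm_params(1),
                          training = TRUE), "at least 2")
})

test_that("post-normalization batch moments equal beta and gamma squared", {
  withr::with_seed(8, {
    x <- matrix(stats::rnorm(200 * 3, mean = 4, sd = 2), 200, 3)
  })
  bp <- batch_norm_params(3)
  bp$gamma <- c(1.5, 0.7, 2); bp$beta <- c(-1, 0, 3)
  out <- batch_norm(x, bp, training = TRUE)
  v <- apply(x, 2, function(col) mean((col - mean(col))^2))
  expect_equal(colMeans(out$y), bp$beta, tolerance = 1e-5)
  # epsilon-corrected expectation of the post-BN population variance
  expect_equal(apply(out$y, 2, function(col) mean((col - mean(col))^2)),
               bp$gamma^2 * v / (v + bp$epsilon), tolerance = 1e-5)
})

test_that("model architecture matches its declared widths", {
  m <- build_fusion_model(48, 56, 5, "basic")
  expect_equal(ncol(m$params$W1), 128L)
  expect_equal(ncol(m$params$W2), 5L)
  expect_equal(m$n_dense_blocks, 0L)
  ext <- build_fusion_model(48, 56, 5, "extended")
  expect_equal(ext$penultimate_width, 850L)
  expect_equal(ncol(ext$params$W1), 850L)
  expect_equal(ext$n_dense_blocks, 3L)
  expect_length(ext$bn_state, 3L)
  expect_error(build_fusion_model(48, 56, 5, "deluxe"), "arg")
  expect_error(build_fusion_model(0, 56, 5), "c_a")
})

test_that("basic-head parameter count matches the closed form", {
  for (dims in list(c(48, 56, 5), c(3, 7, 2), c(128, 64, 9))) {
    m <- build_fusion_model(dims[1], dims[2], dims[3], "basic")
    expect_equal(count_params(m),
                 (dims[1] + dims[2] + 1) * 128 + 129 * dims[3])
  }
})

test_that("softmax predictions are normalized, and zero weights give uniform rows", {
  m <- build_fusion_model(4, 3, 5, "basic", seed = 1)
  a <- matrix(stats::rnorm(12), 3, 4); b <- matrix(stats::rnorm(9), 3, 3)
  p <- predict_proba_features(m, a, b)
  expect_equal(rowSums(p), rep(1, 3), tolerance = 1e-6)
  m0 <- m
  m0$params$W2[] <- 0; m0$params$b2[] <- 0
  p0 <- predict_proba_features(m0, a, b)
  expect_equal(as.numeric(p0), rep(0.2, 15), tolerance = 1e-12)
  expect_error(predict_proba_features(m, matrix(0, 3, 9), b),
               "widths do not match")
})

test_that("analytic gradients agree with finite differences for both heads", {
  withr::with_seed(1, {
    a <- matrix(stats::rnorm(5 * 4), 5); b <- matrix(stats::rnorm(5 * 3), 5)
  })
  y <- c(1L, 2L, 3L, 1L, 2L)
  for (variant in c("basic", "extended")) {
    mm <- build_fusion_model(4, 3, 3, variant, hidden = 6,
                             extended_units = 7, seed = 2)
    lossfn <- function(mod) {
      fw <- fundusfusion:::head_forward(mod, a, b, training = TRUE)
      -mean(log(pmax(fw$probs[cbind(1:5, y)], 1e-12)))
    }
    fw <- fundusfusion:::head_forward(mm, a, b, training = TRUE)
    dlog <- (fw$probs - fundusfusion:::one_hot(y, 3)) / 5
    bw <- fundusfusion:::head_backward(fw$model, fw$cache, dlog)
    for (nm in names(mm$params)) {
      p <- mm$params[[nm]]
      idx <- withr::with_seed(3, sample(length(p), min(3, length(p))))
      for (i in idx) {
        eps <- 1e-5
        m1 <- mm; m1$params[[nm]][i] <- p[i] + eps
        m2 <- mm; m2$params[[nm]][i] <- p[i] - eps
        expect_equal(bw$grads[[nm]][i],
                     (lossfn(m1) - lossfn(m2)) / (2 * eps),
                     tolerance = 1e-5)
      }
    }
  }
})

test_that("training learns a separable feature problem and freezes the backbones", {
  # separable synthetic pooled features: three shifted Gaussian clouds
  withr::with_seed(4, {
    n <- 120
    y <- rep(1:3, each = n / 3)
    centers_a <- matrix(stats::rnorm(3 * 6, sd = 3), 3, 6)
    centers_b <- matrix(stats::rnorm(3 * 4, sd = 3), 3, 4)
    a <- centers_a[y, ] + matrix(stats::rnorm(n * 6), n, 6)
    b <- centers_b[y, ] + matrix(stats::rnorm(n * 4), n, 4)
  })
  feats <- list(a = a, b = b, labels = y, levels = c("c1", "c2", "c3"))
  m <- build_fusion_model(6, 4, 3, "basic", seed = 5)
  res <- train_head(m, NULL, epochs = 15, seed = 6, features = feats)
  expect_gt(res$history$acc[15], res$history$acc[1])
  expect_gt(res$history$acc[15], 0.9)
  expect_equal(nrow(res$history), 15L)

  # epochs = 0: empty history, parameters untouched
  res0 <- train_head(m, NULL, epochs = 0, seed = 6, features = feats)
  expect_equal(nrow(res0$history), 0L)
  expect_identical(res0$model$params, m$params)

  # full path from a manifest: backbone parameters must not move
  ds <- test_dataset()
  bb <- test_backbones()
  before <- lapply(bb, backbone_checksum)
  m2 <- build_fusion_model(bb[[1]]$output_channels,
                           bb[[2]]$output_channels, 5, "basic", seed = 7)
  res2 <- train_head(m2, bb, data = ds$manifest, epochs = 2, seed = 8)
  expect_identical(lapply(bb, backbone_checksum), before)
  expect_equal(nrow(res2$history), 2L)
})

test_that("an overparameterized head memorizes a five-image training set", {
  withr::with_seed(9, {
    a <- matrix(stats::rnorm(5 * 8, sd = 2), 5, 8)
    b <- matrix(stats::rnorm(5 * 8, sd = 2), 5, 8)
  })
  feats <- list(a = a, b = b, labels = 1:5,
                levels = paste0("k", 1:5))
  m <- build_fusion_model(8, 8, 5, "basic", seed = 10)
  res <- train_head(m, NULL, epochs = 200, seed = 11, features = feats,
                    batch_size = 5, val_fraction = 0, lr = 1e-2)
  p <- predict_proba_features(res$model, a, b)
  expect_equal(max.col(p), 1:5)
})

test_that("extended head trains without error and keeps softmax normalization", {
  withr::with_seed(12, {
    y <- rep(1:2, each = 20)
    a <- matrix(stats::rnorm(40 * 5), 40, 5) + 2 * (y == 1)
    b <- matrix(stats::rnorm(40 * 5), 40, 5) - 1 * (y == 2)
  })
  feats <- list(a = a, b = b, labels = y, levels = c("x", "y"))
  m <- build_fusion_model(5, 5, 2, "extended", extended_units = 16,
                          seed = 13)
  res <- train_head(m, NULL, epochs = 25, seed = 14, features = feats,
                    batch_size = 8, lr = 1e-2)
  p <- predict_proba_features(res$model, a, b)
  expect_equal(rowSums(p), rep(1, 40), tolerance = 1e-6)
  expect_gt(tail(res$history$acc, 1), 0.8)
})

test_that("sum and product fusion modes train through their transform layers", {
  withr::with_seed(15, {
    y <- rep(1:2, each = 15)
    a <- matrix(stats::rnorm(30 * 4), 30, 4) + 1.5 * (y == 1)
    b <- matrix(stats::rnorm(30 * 6), 30, 6) - 1.5 * (y == 1)
  })
  feats <- list(a = a, b = b, labels = y, levels = c("p", "q"))
  for (mode in c("sum", "product")) {
    m <- build_fusion_model(4, 6, 2, "basic", fusion_mode = mode, seed = 16)
    res <- train_head(m, NULL, epochs = 10, seed = 17, features = feats,
                      batch_size = 10)
    p <- predict_proba_features(res$model, a, b)
    expect_equal(rowSums(p), rep(1, 30), tolerance = 1e-6)
    expect_gt(tail(res$history$acc, 1), 0.7)
  }
})
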