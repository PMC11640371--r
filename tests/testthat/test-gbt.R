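test_that("softmax cross-entropy gradients and Hessians match closed forms", {
  gh <- compute_grad_hess(matrix(c(1, 0), 1), 1L)
  expect_equal(as.numeric(gh$g), c(0, 0))
  expect_equal(as.numeric(gh$h), c(0, 0))
  gh2 <- compute_grad_hess(matrix(c(0.5, 0.5), 1), 1L)
  expect_equal(as.numeric(gh2$g), c(-0.5, 0.5))
  expect_equal(as.numeric(gh2$h), c(0.25, 0.25))
  expect_error(compute_grad_hess(matrix(c(0.5, 0.5), 1), 3L), "out of range")
})

test_that("gradients agree with finite differences of the log loss", {
  withr::with_seed(1, {
    z <- matrix(stats::rnorm(4 * 3), 4, 3)
  })
  y <- c(1L, 3L, 2L, 1L)
  p <- exp(z) / rowSums(exp(z))
  gh <- compute_grad_hess(p, y)
  loss <- function(zz) {
    pp <- exp(zz) / rowSums(exp(zz))
    -sum(log(pp[cbind(seq_along(y), y)]))
  }
  eps <- 1e-5
  for (i in 1:4) for (k in 1:3) {
    z1 <- z; z1[i, k] <- z[i, k] + eps
    z2 <- z; z2[i, k] <- z[i, k] - eps
    expect_equal(gh$g[i, k], (loss(z1) - loss(z2)) / (2 * eps),
                 tolerance = 1e-4)
  }
})

test_that("leaf weights equal -G/(H + lambda) and shrink with lambda", {
  # hand case: G = -2, H = 1, lambda = 1 -> weight 1
  tree <- fundusfusion:::fit_tree(matrix(0, 2, 1), c(-1, -1), c(0.5, 0.5),
                                  0L, 1, 1e-6)
  expect_equal(tree$weight, 1)
  # regularization monotonicity on a fixed (pure-leaf) structure
  withr::with_seed(2, {
    g <- stats::rnorm(20); h <- stats::runif(20, 0.05, 0.3)
  })
  for (lams in list(c(0, 1), c(0.5, 2), c(1, 10))) {
    w1 <- fundusfusion:::fit_tree(matrix(0, 20, 1), g, h, 0L, lams[1],
                                  1e-6)$weight
    w2 <- fundusfusion:::fit_tree(matrix(0, 20, 1), g, h, 0L, lams[2],
                                  1e-6)$weight
    expect_lte(abs(w2), abs(w1))
  }
})

test_that("an empty ensemble predicts the training class priors", {
  withr::with_seed(3, x <- matrix(stats::rnorm(24), 12, 2))
  y <- rep(1:3, times = c(6, 4, 2))
  ens <- fit_gbt(x, y, gbt_config(n_rounds = 0))
  p <- predict_gbt(ens, x)
  expect_equal(p[1, ], c(`1` = 0.5, `2` = 1 / 3, `3` = 1 / 6),
               ignore_attr = TRUE, tolerance = 1e-12)
  # balanced labels -> uniform probabilities
  ens_b <- fit_gbt(x, rep(1:3, each = 4), gbt_config(n_rounds = 0))
  expect_equal(as.numeric(predict_gbt(ens_b, x[1:2, ])),
               rep(1 / 3, 6), tolerance = 1e-12)
})

test_that("depth-one boosting solves a perfectly split toy", {
  x <- matrix(c(-3, -2, -1, 1, 2, 3), 6, 1)
  y <- c(1L, 1L, 1L, 2L, 2L, 2L)
  ens <- fit_gbt(x, y, gbt_config(n_rounds = 10, max_depth = 1))
  expect_equal(predict_gbt(ens, x, type = "class"),
               as.character(y))
})

test_that("training log loss never increases across boosting rounds", {
  withr::with_seed(4, {
    x <- matrix(stats::rnorm(150 * 5), 150, 5)
    y <- sample(1:3, 150, replace = TRUE)
  })
  ens <- fit_gbt(x, y, gbt_config(n_rounds = 25, eta = 0.3))
  expect_true(all(diff(ens$train_logloss) <= 1e-10))
})

test_that("prediction is additive in the per-round tree outputs", {
  withr::with_seed(5, {
    x <- matrix(stats::rnorm(60 * 3), 60, 3)
    y <- sample(1:3, 60, replace = TRUE)
  })
  ens <- fit_gbt(x, y, gbt_config(n_rounds = 8, eta = 0.25))
  xt <- x[1:7, , drop = FALSE]
  for (k in c(3, 8)) {
    sk <- predict_gbt(ens, xt, n_rounds = k, type = "score")
    sk1 <- predict_gbt(ens, xt, n_rounds = k - 1, type = "score")
    tree_out <- sapply(1:3, function(cl)
      fundusfusion:::predict_tree(ens$trees[[k]][[cl]], xt))
    expect_equal(sk - sk1, 0.25 * tree_out, tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
})

test_that("predicted labels agree with an established boosting implementation", {
  skip_if_not_installed("xgboost")
  withr::with_seed(6, {
    x <- matrix(stats::rnorm(50 * 4), 50, 4)
    y <- ifelse(x[, 1] + x[, 2] > 0, 1L, ifelse(x[, 3] > 0, 2L, 3L))
  })
  cfg <- gbt_config(eta = 0.3, lambda = 1, n_rounds = 20, max_depth = 3)
  ours <- predict_gbt(fit_gbt(x, y, cfg), x, type = "class")
  bst <- xgboost::xgb.train(
    params = list(objective = "multi:softmax", num_class = 3, eta = 0.3,
                  max_depth = 3, lambda = 1, nthread = 1),
    data = xgboost::xgb.DMatrix(x, label = y - 1), nrounds = 20)
  theirs <- as.character(predict(bst, xgboost::xgb.DMatrix(x)) + 1)
  expect_identical(ours, theirs)
})

test_that("ensembles serialize to JSON and back without changing predictions", {
  withr::with_seed(7, {
    x <- matrix(stats::rnorm(40 * 3), 40, 3)
    y <- sample(1:2, 40, replace = TRUE)
  })
  ens <- fit_gbt(x, y, gbt_config(n_rounds = 5))
  path <- tempfile(fileext = ".json")
  write_gbt(ens, path)
  ens2 <- read_gbt(path)
  expect_identical(predict_gbt(ens2, x), predict_gbt(ens, x))
  expect_error(predict_gbt(ens, x[, 1:2, drop = FALSE]), "feature width")
})

test_that("deep-feature representations have the contracted widths", {
  bb <- test_backbones()
  imgs <- list(seeded_image(32, 32, 1), seeded_image(32, 32, 2))
  m <- build_fusion_model(bb[[1]]$output_channels,
                          bb[[2]]$output_channels, 5, "basic", seed = 1)
  pen <- deep_feature_input(m, bb, imgs, "penultimate")
  expect_equal(dim(pen), c(2L, 128L))
  pr <- deep_feature_input(m, bb, imgs, "probabilities")
  expect_equal(dim(pr), c(2L, 5L))
  expect_equal(rowSums(pr), rep(1, 2), tolerance = 1e-6)
  expect_error(deep_feature_input(m, bb, imgs, "logits"), "arg")
})

test_that("identity depthwise kernels reproduce the standard path bit-for-bit", {
  bb <- test_backbones()
  imgs <- list(seeded_image(32, 32, 3))
  m <- build_fusion_model(bb[[1]]$output_channels,
                          bb[[2]]$output_channels, 5, "basic", seed = 2)
  std <- deep_feature_input(m, bb, imgs, "penultimate")
  ident <- deep_feature_input(
    m, bb, imgs, "penultimate",
    depthwise = list(identity_depthwise_kernel(3, bb[[1]]$output_channels),
                     identity_depthwise_kernel(3, bb[[2]]$output_channels)))
  expect_identical(ident, std)
})
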