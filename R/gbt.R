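# Gradient-boosted-tree classification head on deep features. Multiclass
# softmax cross-entropy objective, one depth-limited regression tree per
# class per boosting round, exact greedy split search, second-order leaf
# weights -G/(H + lambda). Deliberately small and transparent: no
# histogram/approximate splits, no column subsampling — exact greedy on
# desk-scale feature matrices.

#' Gradient-boosting configuration
#'
#' @param eta Learning rate (shrinkage) in (0, 1\]; default 0.3.
#' @param lambda L2 regularization on leaf weights, >= 0; default 1.
#' @param n_rounds Number of boosting rounds (trees per class); >= 0;
#'   default 50.
#' @param max_depth Maximum tree depth; >= 1; default 3.
#' @param min_gain Minimal split gain; nodes that cannot improve by more
#'   than this become leaves.
#' @param seed Seed (kept for interface symmetry; the exact-greedy fit is
#'   deterministic given feature order).
#' @return A list of class `gbt_config`.
#' @export
gbt_config <- function(eta = 0.3, lambda = 1, n_rounds = 50L, max_depth = 3L,
                       min_gain = 1e-6, seed = 0) {
  stopifnot(eta > 0, eta <= 1, lambda >= 0, n_rounds >= 0, max_depth >= 1)
  structure(list(eta = eta, lambda = lambda, n_rounds = as.integer(n_rounds),
                 max_depth = as.integer(max_depth), min_gain = min_gain,
                 seed = seed),
            class = "gbt_config")
}

#' Gradients and Hessians of softmax cross-entropy
#'
#' For predicted class probabilities `p` and true labels `y`, the per-sample
#' per-class first and second derivatives of the multiclass log loss with
#' respect to the class scores are `g = p - onehot(y)` and `h = p (1 - p)`.
#'
#' @param probabilities N x K matrix of class probabilities (rows sum to 1).
#' @param labels Integer class indices, 1-based, in 1..K.
#' @return List with matrices `g` and `h`, both N x K.
#' @export
compute_grad_hess <- function(probabilities, labels) {
  p <- as.matrix(probabilities)
  k <- ncol(p)
  if (any(labels < 1L | labels > k)) {
    stop("labels out of range 1..", k, call. = FALSE)
  }
  g <- p
  g[cbind(seq_along(labels), labels)] <-
    g[cbind(seq_along(labels), labels)] - 1
  list(g = g, h = p * (1 - p))
}

# ---- single regression tree (exact greedy, second-order objective) --------

# Returns a tree as a list-of-nodes data structure. Gain for a split is
# 0.5 * (GL^2/(HL+lam) + GR^2/(HR+lam) - G^2/(H+lam)); leaf weight -G/(H+lam).
fit_tree <- function(x, g, h, depth, lambda, min_gain) {
  build <- function(idx, depth_left) {
    G <- sum(g[idx]); H <- sum(h[idx])
    leaf <- list(leaf = TRUE, weight = -G / (H + lambda))
    if (depth_left == 0L || length(idx) < 2L) return(leaf)
    parent_score <- G^2 / (H + lambda)
    best <- list(gain = min_gain)
    for (j in seq_len(ncol(x))) {
      xv <- x[idx, j]
      ord <- order(xv, method = "radix")
      xs <- xv[ord]
      gs <- cumsum(g[idx][ord]); hs <- cumsum(h[idx][ord])
      n <- length(idx)
      cut_ok <- which(xs[-n] < xs[-1])     # only between distinct values
      if (length(cut_ok) == 0L) next
      GL <- gs[cut_ok]; HL <- hs[cut_ok]
      gains <- 0.5 * (GL^2 / (HL + lambda) +
                        (G - GL)^2 / (H - HL + lambda) - parent_score)
      bi <- which.max(gains)
      if (gains[bi] > best$gain) {
        best <- list(gain = gains[bi], feature = j,
                     threshold = (xs[cut_ok[bi]] + xs[cut_ok[bi] + 1L]) / 2)
      }
    }
    if (is.null(best$feature)) return(leaf)
    go_left <- x[idx, best$feature] < best$threshold
    list(leaf = FALSE, feature = best$feature, threshold = best$threshold,
         gain = best$gain,
         left = build(idx[go_left], depth_left - 1L),
         right = build(idx[!go_left], depth_left - 1L))
  }
  build(seq_len(nrow(x)), depth)
}

predict_tree <- function(tree, x) {
  out <- numeric(nrow(x))
  rec <- function(node, idx) {
    if (length(idx) == 0L) return()
    if (node$leaf) {
      out[idx] <<- node$weight
    } else {
      go_left <- x[idx, node$feature] < node$threshold
      rec(node$left, idx[go_left])
      rec(node$right, idx[!go_left])
    }
  }
  rec(tree, seq_len(nrow(x)))
  out
}

tree_leaf_weights <- function(tree) {
  if (tree$leaf) return(tree$weight)
  c(tree_leaf_weights(tree$left), tree_leaf_weights(tree$right))
}

#' Fit a gradient-boosted-tree ensemble on feature vectors
#'
#' Boosting starts from per-class base scores equal to the log class priors
#' (so an empty ensemble predicts the training class distribution). Each
#' round computes softmax probabilities, the per-class gradients and
#' Hessians ([compute_grad_hess()]), fits one exact-greedy regression tree
#' per class, and adds its predictions scaled by `eta`.
#'
#' @param features N x D numeric matrix.
#' @param labels Class labels: a factor, or integer indices 1..K.
#' @param config A [gbt_config()].
#' @return A list of class `gbt_ensemble` with the per-class tree sequences,
#'   base scores, class levels, config, and the per-round training log loss.
#' @export
fit_gbt <- function(features, labels, config = gbt_config()) {
  stopifnot(inherits(config, "gbt_config"))
  x <- as.matrix(features)
  if (anyNA(x) || any(!is.finite(x))) stop("features must be finite",
                                           call. = FALSE)
  if (is.factor(labels) || is.character(labels)) {
    levels_ <- if (is.factor(labels)) levels(labels) else sort(unique(labels))
    y <- match(as.character(labels), levels_)
  } else {
    y <- as.integer(labels)
    levels_ <- as.character(seq_len(max(y)))
  }
  k <- length(levels_)
  if (length(unique(y)) < 2L) stop("need at least two classes", call. = FALSE)
  prior <- tabulate(y, k) / length(y)
  base <- log(pmax(prior, 1e-12))
  scores <- matrix(base, nrow(x), k, byrow = TRUE)
  trees <- vector("list", config$n_rounds)
  logloss <- numeric(config$n_rounds)
  for (t in seq_len(config$n_rounds)) {
    p <- softmax_rows(scores)
    gh <- compute_grad_hess(p, y)
    round_trees <- vector("list", k)
    for (cls in seq_len(k)) {
      tree <- fit_tree(x, gh$g[, cls], gh$h[, cls], config$max_depth,
                       config$lambda, config$min_gain)
      scores[, cls] <- scores[, cls] + config$eta * predict_tree(tree, x)
      round_trees[[cls]] <- tree
    }
    trees[[t]] <- round_trees
    p_new <- softmax_rows(scores)
    logloss[t] <- -mean(log(pmax(p_new[cbind(seq_along(y), y)], 1e-12)))
  }
  structure(list(trees = trees, base_score = base, levels = levels_,
                 n_features = ncol(x), config = config,
                 train_logloss = logloss),
            class = "gbt_ensemble")
}

#' Predict with a gradient-boosted-tree ensemble
#'
#' The score of each class is the base score plus `eta` times the sum of
#' that class's tree outputs (additive ensemble); probabilities are the
#' softmax of the scores.
#'
#' @param ensemble A [fit_gbt()] object.
#' @param features N x D matrix with the training feature width.
#' @param n_rounds Optionally truncate the ensemble to its first `n_rounds`
#'   rounds (used to check additivity).
#' @param type `"prob"` (default), `"score"` (pre-softmax margins) or
#'   `"class"` (predicted labels).
#' @return N x K matrix, or a character vector for `type = "class"`.
#' @export
predict_gbt <- function(ensemble, features, n_rounds = NULL,
                        type = c("prob", "score", "class")) {
  type <- match.arg(type)
  stopifnot(inherits(ensemble, "gbt_ensemble"))
  x <- as.matrix(features)
  if (ncol(x) != ensemble$n_features) {
    stop("feature width ", ncol(x), " does not match training width ",
         ensemble$n_features, call. = FALSE)
  }
  k <- length(ensemble$base_score)
  rounds <- if (is.null(n_rounds)) length(ensemble$trees) else
    min(n_rounds, length(ensemble$trees))
  scores <- matrix(ensemble$base_score, nrow(x), k, byrow = TRUE)
  eta <- ensemble$config$eta
  for (t in seq_len(rounds)) {
    for (cls in seq_len(k)) {
      scores[, cls] <- scores[, cls] +
        eta * predict_tree(ensemble$trees[[t]][[cls]], x)
    }
  }
  switch(type,
         score = scores,
         prob = softmax_rows(scores),
         class = ensemble$levels[max.col(softmax_rows(scores),
                                         ties.method = "first")])
}

#' Serialize an ensemble to a JSON tree dump
#'
#' @param ensemble A [fit_gbt()] object.
#' @param path Output JSON file.
#' @return `path` invisibly; `read_gbt()` restores the ensemble.
#' @export
write_gbt <- function(ensemble, path) {
  stopifnot(inherits(ensemble, "gbt_ensemble"))
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  writeLines(jsonlite::serializeJSON(unclass(ensemble), digits = 17), path)
  invisible(path)
}

#' @rdname write_gbt
#' @export
read_gbt <- function(path) {
  obj <- jsonlite::unserializeJSON(paste(readLines(path, warn = FALSE),
                                         collapse = "\n"))
  class(obj$config) <- "gbt_config"
  structure(obj, class = "gbt_ensemble")
}

#' Deep-feature input for the boosted head
#'
#' Computes the feature representation the tree ensemble consumes:
#' `"penultimate"` (default) takes the activations of the fusion head's last
#' hidden dense layer; `"probabilities"` takes its softmax outputs. With
#' `depthwise` kernels supplied, each backbone's feature map is passed
#' through one depthwise convolution before pooling (a feature-map
#' transform; identity kernels reproduce the standard path exactly).
#'
#' @param model A trained [build_fusion_model()].
#' @param backbones List of two [build_backbone()] objects.
#' @param batch Images accepted by [extract()].
#' @param representation `"penultimate"` or `"probabilities"`.
#' @param depthwise Optional list of two kernel arrays (kh x kw x C, one per
#'   backbone), e.g. [identity_depthwise_kernel()].
#' @return N x D feature matrix (D = penultimate width or num_classes).
#' @export
deep_feature_input <- function(model, backbones, batch,
                               representation = c("penultimate",
                                                  "probabilities"),
                               depthwise = NULL) {
  representation <- match.arg(representation)
  fa <- extract(backbones[[1]], batch)
  fb <- extract(backbones[[2]], batch)
  if (!is.null(depthwise)) {
    fa <- apply_depthwise_batch(fa, depthwise[[1]])
    fb <- apply_depthwise_batch(fb, depthwise[[2]])
  }
  fw <- head_forward(model, gap(fa), gap(fb), training = FALSE)
  if (representation == "penultimate") fw$penultimate else fw$probs
}

#' @rdname deep_feature_input
#' @param k Kernel size (odd); @param channels number of channels.
#' @export
identity_depthwise_kernel <- function(k, channels) {
  w <- array(0, c(k, k, channels))
  w[(k + 1L) %/% 2L, (k + 1L) %/% 2L, ] <- 1
  w
}

apply_depthwise_batch <- function(fmap, w) {
  d <- dim(fmap)
  out <- NULL
  for (i in seq_len(d[1])) {
    y <- depthwise_conv2d(array(fmap[i, , , ], d[2:4]), w, stride = 1L)
    if (is.null(out)) out <- array(0, c(d[1], dim(y)))
    out[i, , , ] <- y
  }
  out
}
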