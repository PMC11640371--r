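# Feature-fusion classification head. Pooled features from the two frozen
# backbones are combined (concatenation by default; element-wise sum or
# product via a linear feature-transform layer that aligns widths) and fed
# to a dense head: either the basic head, Dense(128, relu) -> Dense(K,
# softmax), or the extended head, three dense blocks (per-channel depthwise
# scaling, degenerate max pooling, ReLU, batch normalization, additive skip)
# followed by Dense(850, relu) -> Dense(K, softmax). Only head parameters
# are ever trained; backbones stay frozen.

fusion_modes <- c("concat", "sum", "product")

#' Batch-normalization parameter set
#'
#' @param n_features Number of features normalized independently.
#' @param epsilon Small positive constant added to the variance for
#'   numerical stability.
#' @param momentum Running-statistics update rate in training mode.
#' @return A list of class `batch_norm_params` with learned `gamma` (scale)
#'   and `beta` (shift), running `mean` and `var`, `epsilon`, `momentum`.
#' @export
batch_norm_params <- function(n_features, epsilon = 1e-5, momentum = 0.1) {
  stopifnot(n_features >= 1, epsilon > 0)
  structure(list(gamma = rep(1, n_features), beta = rep(0, n_features),
                 mean = rep(0, n_features), var = rep(1, n_features),
                 epsilon = epsilon, momentum = momentum),
            class = "batch_norm_params")
}

#' Batch normalization over a feature batch
#'
#' In training mode the mini-batch mean and (population) variance are used
#' to standardize each feature, and the running statistics are updated; in
#' inference mode the running statistics are used. The output is
#' `gamma * x_hat + beta`.
#'
#' @param x An N x D numeric matrix (rows = samples).
#' @param params A [batch_norm_params()].
#' @param training Logical; training mode requires N >= 2.
#' @return A list with `y` (the normalized batch) and `params` (with updated
#'   running statistics when `training = TRUE`).
#' @export
batch_norm <- function(x, params, training = FALSE) {
  stopifnot(inherits(params, "batch_norm_params"))
  x <- as.matrix(x)
  if (ncol(x) != length(params$gamma)) {
    stop("feature width does not match batch_norm_params", call. = FALSE)
  }
  if (training) {
    if (nrow(x) < 2L) {
      stop("training-mode batch normalization needs a batch of at least 2",
           call. = FALSE)
    }
    mu <- colMeans(x)
    xc <- sweep(x, 2L, mu)
    v <- colMeans(xc^2)
    params$mean <- (1 - params$momentum) * params$mean + params$momentum * mu
    params$var <- (1 - params$momentum) * params$var + params$momentum * v
  } else {
    mu <- params$mean
    v <- params$var
    xc <- sweep(x, 2L, mu)
  }
  xhat <- sweep(xc, 2L, sqrt(v + params$epsilon), "/")
  y <- sweep(sweep(xhat, 2L, params$gamma, "*"), 2L, params$beta, "+")
  list(y = y, params = params, xhat = xhat, var = v)
}

#' Combine two pooled feature batches
#'
#' `concat` appends the feature axes; `sum` and `product` combine
#' element-wise after an optional linear feature-transform layer aligns the
#' two widths (identity when widths already agree and no transform is
#' given).
#'
#' @param a,b N x C matrices (equal N). Vectors are treated as single rows.
#' @param mode One of `"concat"`, `"sum"`, `"product"`.
#' @param transform Optional list with `Wa`, `ba`, `Wb`, `bb` mapping both
#'   inputs to a common width (required for sum/product when widths differ).
#' @return The fused N x C' matrix.
#' @export
fuse <- function(a, b, mode = c("concat", "sum", "product"), transform = NULL) {
  mode <- match.arg(mode)
  if (is.null(dim(a))) a <- matrix(a, nrow = 1L)
  if (is.null(dim(b))) b <- matrix(b, nrow = 1L)
  if (nrow(a) != nrow(b)) stop("batch sizes differ", call. = FALSE)
  if (mode == "concat") return(cbind(a, b))
  if (!is.null(transform)) {
    a <- sweep(a %*% transform$Wa, 2L, transform$ba, "+")
    b <- sweep(b %*% transform$Wb, 2L, transform$bb, "+")
  }
  if (ncol(a) != ncol(b)) {
    stop("sum/product fusion needs equal widths; supply a feature transform",
         call. = FALSE)
  }
  if (mode == "sum") a + b else a * b
}

glorot_mat <- function(din, dout) {
  matrix(stats::rnorm(din * dout, 0, sqrt(2 / (din + dout))), din, dout)
}

#' Build a feature-fusion classification model
#'
#' @param c_a,c_b Channel counts of the two pooled feature inputs.
#' @param num_classes Number of output classes (default 5: normal, diabetic
#'   retinopathy, hypertensive retinopathy, glaucoma, contrast).
#' @param variant `"basic"`: fuse -> Dense(`hidden` = 128, relu) ->
#'   Dense(K, softmax). `"extended"`: fuse -> 3 dense blocks (depthwise
#'   per-channel scaling, degenerate max pooling on the 1 x 1 spatial grid,
#'   ReLU, batch normalization, additive skip) -> Dense(`extended_units` =
#'   850, relu) -> Dense(K, softmax).
#' @param fusion_mode `"concat"` (default), `"sum"` or `"product"`; the
#'   non-concat modes add a trainable linear feature-transform layer
#'   aligning both inputs to width `transform_width`.
#' @param seed Seed for weight initialization.
#' @param hidden Width of the basic head's hidden dense layer.
#' @param extended_units Width of the extended head's penultimate dense
#'   layer.
#' @param transform_width Common width for sum/product fusion (default
#'   `max(c_a, c_b)`).
#' @return A list of class `fusion_model`.
#' @export
build_fusion_model <- function(c_a, c_b, num_classes = 5L,
                               variant = c("basic", "extended"),
                               fusion_mode = c("concat", "sum", "product"),
                               seed = 0, hidden = 128L, extended_units = 850L,
                               transform_width = NULL) {
  variant <- match.arg(variant)
  fusion_mode <- match.arg(fusion_mode)
  stopifnot(c_a >= 1, c_b >= 1, num_classes >= 2)
  withr::with_seed(seed, {
    params <- list()
    if (fusion_mode == "concat") {
      d_in <- c_a + c_b
    } else {
      d_in <- if (is.null(transform_width)) max(c_a, c_b) else transform_width
      params$Wa <- glorot_mat(c_a, d_in); params$ba <- rep(0, d_in)
      params$Wb <- glorot_mat(c_b, d_in); params$bb <- rep(0, d_in)
    }
    bn_state <- NULL
    if (variant == "basic") {
      params$W1 <- glorot_mat(d_in, hidden); params$b1 <- rep(0, hidden)
      params$W2 <- glorot_mat(hidden, num_classes)
      params$b2 <- rep(0, num_classes)
      penult <- hidden
    } else {
      bn_state <- list()
      for (k in 1:3) {
        params[[paste0("dw_w", k)]] <- rep(1, d_in) +
          stats::rnorm(d_in, 0, 0.05)
        params[[paste0("dw_b", k)]] <- rep(0, d_in)
        params[[paste0("bn_gamma", k)]] <- rep(1, d_in)
        params[[paste0("bn_beta", k)]] <- rep(0, d_in)
        bn_state[[k]] <- list(mean = rep(0, d_in), var = rep(1, d_in),
                              epsilon = 1e-5, momentum = 0.1)
      }
      params$W1 <- glorot_mat(d_in, extended_units)
      params$b1 <- rep(0, extended_units)
      params$W2 <- glorot_mat(extended_units, num_classes)
      params$b2 <- rep(0, num_classes)
      penult <- extended_units
    }
    structure(list(variant = variant, fusion_mode = fusion_mode,
                   c_a = c_a, c_b = c_b, d_in = d_in,
                   num_classes = num_classes, hidden = hidden,
                   extended_units = extended_units,
                   penultimate_width = penult,
                   n_dense_blocks = if (variant == "extended") 3L else 0L,
                   params = params, bn_state = bn_state, seed = seed),
              class = "fusion_model")
  })
}

#' Total trainable parameter count of a fusion model
#' @param model A [build_fusion_model()] object.
#' @return Integer parameter count.
#' @export
count_params <- function(model) {
  stopifnot(inherits(model, "fusion_model"))
  sum(vapply(model$params, length, integer(1)))
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

# forward through the fusion + head. Returns logits, probabilities,
# penultimate activations, a backprop cache, and the (possibly updated)
# model when training-mode batch norm ran.
head_forward <- function(model, a, b, training = FALSE) {
  p <- model$params
  if (!is.null(model$feat_norm)) {
    fn <- model$feat_norm
    a <- sweep(sweep(a, 2L, fn$mu_a), 2L, fn$sd_a, "/")
    b <- sweep(sweep(b, 2L, fn$mu_b), 2L, fn$sd_b, "/")
  }
  cache <- list(a = a, b = b)
  if (model$fusion_mode == "concat") {
    x <- cbind(a, b)
  } else {
    ta <- sweep(a %*% p$Wa, 2L, p$ba, "+")
    tb <- sweep(b %*% p$Wb, 2L, p$bb, "+")
    cache$ta <- ta; cache$tb <- tb
    x <- if (model$fusion_mode == "sum") ta + tb else ta * tb
  }
  cache$fused <- x
  if (model$variant == "extended") {
    cache$blocks <- vector("list", 3L)
    for (k in 1:3) {
      s <- x
      z <- sweep(sweep(x, 2L, p[[paste0("dw_w", k)]], "*"),
                 2L, p[[paste0("dw_b", k)]], "+")
      # max pooling over the 1 x 1 spatial grid of a vector input is the
      # identity; ReLU then batch norm then the in-block additive skip
      act <- relu(z)
      st <- model$bn_state[[k]]
      bnp <- structure(list(gamma = p[[paste0("bn_gamma", k)]],
                            beta = p[[paste0("bn_beta", k)]],
                            mean = st$mean, var = st$var,
                            epsilon = st$epsilon, momentum = st$momentum),
                       class = "batch_norm_params")
      bn <- batch_norm(act, bnp, training = training)
      if (training) {
        model$bn_state[[k]]$mean <- bn$params$mean
        model$bn_state[[k]]$var <- bn$params$var
      }
      cache$blocks[[k]] <- list(x_in = s, z = z, act = act,
                                xhat = bn$xhat, var = bn$var)
      x <- bn$y + s
    }
  }
  z1 <- sweep(x %*% p$W1, 2L, p$b1, "+")
  h1 <- relu(z1)
  logits <- sweep(h1 %*% p$W2, 2L, p$b2, "+")
  cache$head_in <- x; cache$z1 <- z1; cache$h1 <- h1
  list(logits = logits, probs = softmax_rows(logits), penultimate = h1,
       cache = cache, model = model)
}

# backward pass for the cross-entropy loss; returns gradients named like
# model$params. `donehot` is (probs - Y)/N.
head_backward <- function(model, cache, dlogits, training = TRUE) {
  p <- model$params
  g <- list()
  g$W2 <- crossprod(cache$h1, dlogits)
  g$b2 <- colSums(dlogits)
  dh1 <- tcrossprod(dlogits, p$W2)
  dz1 <- dh1 * (cache$z1 > 0)
  g$W1 <- crossprod(cache$head_in, dz1)
  g$b1 <- colSums(dz1)
  dx <- tcrossprod(dz1, p$W1)
  if (model$variant == "extended") {
    for (k in 3:1) {
      blk <- cache$blocks[[k]]
      gamma <- p[[paste0("bn_gamma", k)]]
      # through the skip: dx splits into the BN path and the identity path
      dbn <- dx
      g[[paste0("bn_gamma", k)]] <- colSums(dbn * blk$xhat)
      g[[paste0("bn_beta", k)]] <- colSums(dbn)
      n <- nrow(dbn)
      inv_sd <- 1 / sqrt(blk$var + model$bn_state[[k]]$epsilon)
      dxhat <- sweep(dbn, 2L, gamma, "*")
      dact <- if (training) {
        # batch statistics participate in the training-mode forward pass
        sweep(dxhat - matrix(colMeans(dxhat), n, ncol(dxhat), byrow = TRUE) -
                blk$xhat * matrix(colMeans(dxhat * blk$xhat), n,
                                  ncol(dxhat), byrow = TRUE),
              2L, inv_sd, "*")
      } else {
        # inference-mode BN is a fixed affine map
        sweep(dxhat, 2L, inv_sd, "*")
      }
      dz <- dact * (blk$z > 0)
      g[[paste0("dw_w", k)]] <- colSums(dz * blk$x_in)
      g[[paste0("dw_b", k)]] <- colSums(dz)
      dx <- sweep(dz, 2L, p[[paste0("dw_w", k)]], "*") + dx
    }
  }
  if (model$fusion_mode == "concat") {
    g_a <- dx[, seq_len(model$c_a), drop = FALSE]
    g_b <- dx[, model$c_a + seq_len(model$c_b), drop = FALSE]
  } else {
    if (model$fusion_mode == "sum") {
      dta <- dx; dtb <- dx
    } else {
      dta <- dx * cache$tb; dtb <- dx * cache$ta
    }
    g$Wa <- crossprod(cache$a, dta); g$ba <- colSums(dta)
    g$Wb <- crossprod(cache$b, dtb); g$bb <- colSums(dtb)
    g_a <- tcrossprod(dta, p$Wa); g_b <- tcrossprod(dtb, p$Wb)
  }
  if (!is.null(model$feat_norm)) {
    # gradients with respect to the raw (unstandardized) pooled features
    g_a <- sweep(g_a, 2L, model$feat_norm$sd_a, "/")
    g_b <- sweep(g_b, 2L, model$feat_norm$sd_b, "/")
  }
  list(grads = g, d_a = g_a, d_b = g_b)
}

# BN backward above uses the training-mode batch statistics; in inference
# mode (Grad-CAM) the BN layer is a fixed affine map, handled separately.

one_hot <- function(y, k) {
  m <- matrix(0, length(y), k)
  m[cbind(seq_along(y), y)] <- 1
  m
}

#' Class-probability predictions
#'
#' Runs the frozen backbones and the fusion head in inference mode.
#'
#' @param model A [build_fusion_model()] (typically after [train_head()]).
#' @param backbones A list of two [build_backbone()] objects.
#' @param batch Images accepted by [extract()].
#' @return An N x num_classes matrix of probabilities; rows sum to 1.
#' @export
predict_proba <- function(model, backbones, batch) {
  a <- gap(extract(backbones[[1]], batch))
  b <- gap(extract(backbones[[2]], batch))
  predict_proba_features(model, a, b)
}

#' @rdname predict_proba
#' @param a,b Precomputed pooled feature matrices (N x c_a, N x c_b).
#' @export
predict_proba_features <- function(model, a, b) {
  stopifnot(inherits(model, "fusion_model"))
  if (ncol(a) != model$c_a || ncol(b) != model$c_b) {
    stop("pooled feature widths do not match the model", call. = FALSE)
  }
  head_forward(model, a, b, training = FALSE)$probs
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(grads)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

ce_loss_acc <- function(probs, y) {
  idx <- cbind(seq_along(y), y)
  list(loss = -mean(log(pmax(probs[idx], 1e-12))),
       acc = mean(max.col(probs, ties.method = "first") == y))
}

# stratified index split: returns val indices
stratified_val_idx <- function(y, fraction, seed) {
  withr::with_seed(seed, {
    unlist(lapply(unique(y), function(cl) {
      idx <- which(y == cl)
      n_val <- floor(fraction * length(idx))
      if (n_val == 0L) integer(0) else sample(idx, n_val)
    }))
  })
}

#' Extract and pool features for a manifest
#'
#' Reads every image listed in a dataset manifest and computes pooled
#' features under both backbones. Used internally by [train_head()] and
#' [run_pipeline()]; exposed because feature extraction is the pipeline's
#' dominant cost and callers may want to cache the result.
#'
#' @param backbones List of two [build_backbone()] objects.
#' @param manifest Data frame with columns `path`, `label`.
#' @return List with matrices `a`, `b` (N x C each) and integer `labels`
#'   (1-based class indices over [class_labels()] levels present).
#' @export
manifest_features <- function(backbones, manifest) {
  imgs <- lapply(manifest$path, read_image)
  lv <- intersect(class_labels(), unique(manifest$label))
  list(a = gap(extract(backbones[[1]], imgs)),
       b = gap(extract(backbones[[2]], imgs)),
       labels = match(manifest$label, lv), levels = lv)
}

#' Train the fusion head
#'
#' Minimizes categorical cross-entropy with the Adam optimizer over the
#' head parameters only; the backbones are frozen by construction (their
#' parameters are never touched, which [backbone_checksum()] can verify).
#' A stratified validation split is carved out of the training data and
#' per-epoch loss/accuracy for both splits are recorded.
#'
#' @param model A [build_fusion_model()].
#' @param backbones List of two [build_backbone()] objects.
#' @param data A dataset manifest (columns `path`, `label`, `split`); rows
#'   with `split == "train"` are used.
#' @param epochs Number of training epochs (0 returns the model unchanged
#'   with an empty history).
#' @param seed Seed controlling the validation split and batch shuffling.
#' @param batch_size Minibatch size.
#' @param lr Adam learning rate.
#' @param val_fraction Stratified validation fraction of the training data.
#' @param features Optional precomputed [manifest_features()] for the
#'   training rows (bypasses image reading and extraction).
#' @param standardize Standardize each pooled feature to zero mean and unit
#'   variance using training-set statistics before the head (stored in the
#'   model and applied automatically at prediction time). Default `TRUE`.
#' @param verbose Print one log line per epoch.
#' @return A list with `model` (trained) and `history` (data frame with
#'   columns epoch, loss, acc, val_loss, val_acc).
#' @export
train_head <- function(model, backbones, data = NULL, epochs = 15L, seed = 0,
                       batch_size = 32L, lr = 1e-3, val_fraction = 0.1,
                       features = NULL, standardize = TRUE, verbose = FALSE) {
  stopifnot(inherits(model, "fusion_model"))
  history <- data.frame(epoch = integer(0), loss = numeric(0),
                        acc = numeric(0), val_loss = numeric(0),
                        val_acc = numeric(0))
  if (epochs == 0L) return(list(model = model, history = history))
  if (is.null(features)) {
    if (is.null(data)) stop("either `data` or `features` is required",
                            call. = FALSE)
    tr <- data[data$split == "train", , drop = FALSE]
    if (nrow(tr) == 0L) stop("training split is empty", call. = FALSE)
    features <- manifest_features(backbones, tr)
  }
  a <- features$a; b <- features$b; y <- features$labels
  if (!is.null(features$levels)) model$levels <- features$levels
  if (length(unique(y)) < 2L) stop("need at least two classes to train",
                                   call. = FALSE)
  val_idx <- stratified_val_idx(y, val_fraction, seed)
  tr_idx <- setdiff(seq_along(y), val_idx)
  if (standardize && is.null(model$feat_norm)) {
    at <- a[tr_idx, , drop = FALSE]; bt <- b[tr_idx, , drop = FALSE]
    model$feat_norm <- list(
      mu_a = colMeans(at), sd_a = pmax(apply(at, 2L, stats::sd), 1e-8),
      mu_b = colMeans(bt), sd_b = pmax(apply(bt, 2L, stats::sd), 1e-8))
  }
  state <- adam_init(model$params)
  for (ep in seq_len(epochs)) {
    order_idx <- withr::with_seed(seed + 7919L * ep, sample(tr_idx))
    for (start in seq(1L, length(order_idx), by = batch_size)) {
      bi <- order_idx[start:min(start + batch_size - 1L, length(order_idx))]
      if (length(bi) < 2L) next   # training-mode BN needs >= 2 samples
      fw <- head_forward(model, a[bi, , drop = FALSE], b[bi, , drop = FALSE],
                         training = TRUE)
      model <- fw$model
      dlogits <- (fw$probs - one_hot(y[bi], model$num_classes)) / length(bi)
      bw <- head_backward(model, fw$cache, dlogits)
      upd <- adam_step(model$params, bw$grads, state, lr)
      model$params <- upd$params
      state <- upd$state
    }
    tr_eval <- ce_loss_acc(
      head_forward(model, a[tr_idx, , drop = FALSE],
                   b[tr_idx, , drop = FALSE])$probs, y[tr_idx])
    if (length(val_idx) > 0L) {
      va_eval <- ce_loss_acc(
        head_forward(model, a[val_idx, , drop = FALSE],
                     b[val_idx, , drop = FALSE])$probs, y[val_idx])
    } else {
      va_eval <- list(loss = NA_real_, acc = NA_real_)
    }
    history <- rbind(history, data.frame(
      epoch = ep, loss = tr_eval$loss, acc = tr_eval$acc,
      val_loss = va_eval$loss, val_acc = va_eval$acc))
    if (verbose) {
      message(sprintf(
        "epoch %2d  loss %.4f  acc %.3f  val_loss %.4f  val_acc %.3f",
        ep, tr_eval$loss, tr_eval$acc, va_eval$loss, va_eval$acc))
    }
  }
  list(model = model, history = history)
}
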