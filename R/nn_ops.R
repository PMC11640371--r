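# Minimal convolutional forward primitives used by the frozen feature
# extractors. Convolutions are evaluated as im2col matrix products so the
# heavy lifting is a single BLAS call per layer. Single-image layout is
# height x width x channels; batches are lists or 4-d arrays N x H x W x C.

# zero-pad a H x W x C array spatially
pad_spatial <- function(x, ph, pw) {
  if (ph == 0 && pw == 0) return(x)
  d <- dim(x)
  out <- array(0, c(d[1] + 2 * ph, d[2] + 2 * pw, d[3]))
  out[ph + seq_len(d[1]), pw + seq_len(d[2]), ] <- x
  out
}

# im2col: returns a (out_h*out_w) x (kh*kw*C) matrix whose rows enumerate
# output positions (rows fastest), columns enumerate (ki, kj, c) patches in
# column-major order — matching matrix(w, kh*kw*C, O) for w of dim
# (kh, kw, C, O).
im2col <- function(x, kh, kw, stride) {
  d <- dim(x); Hp <- d[1]; Wp <- d[2]; C <- d[3]
  out_h <- (Hp - kh) %/% stride + 1L
  out_w <- (Wp - kw) %/% stride + 1L
  rows0 <- rep(seq.int(1L, by = stride, length.out = out_h), times = out_w)
  cols0 <- rep(seq.int(1L, by = stride, length.out = out_w), each = out_h)
  base <- rows0 + (cols0 - 1L) * Hp
  off <- as.vector(outer(0:(kh - 1L), (0:(kw - 1L)) * Hp, "+"))
  offc <- rep(off, C) + rep((0:(C - 1L)) * Hp * Wp, each = kh * kw)
  idx <- outer(base, offc, "+")
  matrix(x[idx], nrow = out_h * out_w,
         dimnames = NULL)
}

# standard 2-d convolution, "same"-style padding of floor(k/2)
conv2d <- function(x, w, b = NULL, stride = 1L) {
  kh <- dim(w)[1]; kw <- dim(w)[2]; O <- dim(w)[4]
  stopifnot(dim(x)[3] == dim(w)[3])
  xp <- pad_spatial(x, kh %/% 2L, kw %/% 2L)
  M <- im2col(xp, kh, kw, stride)
  Y <- M %*% matrix(w, ncol = O)
  if (!is.null(b)) Y <- sweep(Y, 2L, b, "+")
  out_h <- (dim(xp)[1] - kh) %/% stride + 1L
  out_w <- (dim(xp)[2] - kw) %/% stride + 1L
  array(Y, c(out_h, out_w, O))
}

# depthwise 2-d convolution; w has dim (kh, kw, C)
depthwise_conv2d <- function(x, w, b = NULL, stride = 1L) {
  kh <- dim(w)[1]; kw <- dim(w)[2]; C <- dim(w)[3]
  stopifnot(dim(x)[3] == C)
  xp <- pad_spatial(x, kh %/% 2L, kw %/% 2L)
  M <- im2col(xp, kh, kw, stride)          # columns blocked per channel
  out_h <- (dim(xp)[1] - kh) %/% stride + 1L
  out_w <- (dim(xp)[2] - kw) %/% stride + 1L
  k2 <- kh * kw
  Y <- matrix(0, out_h * out_w, C)
  for (cc in seq_len(C)) {
    Y[, cc] <- M[, (cc - 1L) * k2 + seq_len(k2), drop = FALSE] %*%
      as.vector(w[, , cc])
  }
  if (!is.null(b)) Y <- sweep(Y, 2L, b, "+")
  array(Y, c(out_h, out_w, C))
}

relu <- function(x) pmax(x, 0)
relu6 <- function(x) pmin(pmax(x, 0), 6)
sigmoid <- function(x) 1 / (1 + exp(-x))
swish <- function(x) x * sigmoid(x)

apply_activation <- function(x, act) {
  switch(act,
         relu = relu(x), relu6 = relu6(x), swish = swish(x),
         linear = x,
         stop("unknown activation: ", act, call. = FALSE))
}

# inference-mode batch normalization over the channel axis of a H x W x C map
bn_infer_map <- function(x, bn) {
  scale <- bn$gamma / sqrt(bn$var + bn$eps)
  shift <- bn$beta - bn$mean * scale
  d <- dim(x)
  array(sweep(sweep(matrix(x, ncol = d[3]), 2L, scale, "*"),
              2L, shift, "+"), d)
}

#' Global average pooling
#'
#' Collapses each channel of a feature map to its arithmetic mean over both
#' spatial axes.
#'
#' @param fmap Either a single feature map (height x width x channels) or a
#'   batch (n x height x width x channels).
#' @return For a single map, a numeric vector of length `channels`; for a
#'   batch, an n x channels matrix.
#' @export
gap <- function(fmap) {
  d <- dim(fmap)
  if (is.null(d) || !(length(d) %in% c(3L, 4L))) {
    stop("`fmap` must be a 3-d feature map or a 4-d batch", call. = FALSE)
  }
  if (anyNA(fmap) || any(!is.finite(fmap))) {
    stop("feature map contains non-finite values", call. = FALSE)
  }
  if (length(d) == 3L) {
    colMeans(matrix(fmap, ncol = d[3]))
  } else {
    t(apply(fmap, 1L, function(m) colMeans(matrix(m, ncol = d[4]))))
  }
}
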