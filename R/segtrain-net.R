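# Built-in small encoder-decoder segmentation network ("tinyunet").
#
# A two-level U-shaped convolutional network operating on (C, H*W)
# feature matrices (pixels in column-major raster order). Convolutions
# are 3x3 same-padding implemented via im2col + BLAS matrix products, so
# forward and backward passes are plain matrix algebra and fully
# deterministic on one thread. Downsampling is 2x average pooling,
# upsampling nearest-neighbour, with skip concatenation at each level.

TINYUNET_CHANNELS <- list(enc1 = 8L, enc2 = 16L, bottleneck = 24L,
                          dec2 = 16L, dec1 = 12L, classes = 5L)

# Precomputed index maps for one (H, W): pooling child indices and
# upsampling parent indices at each pyramid level.
net_geometry <- function(H, W) {
  stopifnot(H %% 4 == 0, W %% 4 == 0)
  level <- function(h, w) {
    pool <- NULL; parent <- NULL
    if (h %% 2 == 0 && w %% 2 == 0) {
      r2 <- seq(1, h, by = 2); c2 <- seq(1, w, by = 2)
      base <- as.vector(outer(r2, (c2 - 1) * h, "+"))
      pool <- list(base, base + 1L, base + h, base + h + 1L)
      # parent (coarse) index of each fine pixel, for nearest upsampling
      pr <- rep(seq_len(h / 2), each = 2)[seq_len(h)]
      pc <- rep(seq_len(w / 2), each = 2)[seq_len(w)]
      parent <- as.vector(outer(pr, (pc - 1) * (h / 2), "+"))
    }
    list(h = h, w = w, pool = pool, parent = parent)
  }
  list(full = level(H, W), half = level(H / 2, W / 2),
       quarter = level(H / 4, W / 4))
}

conv3_fwd <- function(X, Wt, b, g, relu = TRUE) {
  cpp_conv3_fwd(X, g$h, g$w, Wt, b, relu)
}

conv3_bwd <- function(X, Wt, dZ, g, need_dX = TRUE) {
  cpp_conv3_bwd(X, g$h, g$w, Wt, dZ, need_dX)
}

pool2_fwd <- function(X, g) {
  p <- g$pool
  (X[, p[[1]], drop = FALSE] + X[, p[[2]], drop = FALSE] +
     X[, p[[3]], drop = FALSE] + X[, p[[4]], drop = FALSE]) / 4
}

pool2_bwd <- function(dP, g) {
  p <- g$pool
  dX <- matrix(0, nrow(dP), g$h * g$w)
  q <- dP / 4
  for (k in 1:4) dX[, p[[k]]] <- q
  dX
}

up2_fwd <- function(X, g_fine) X[, g_fine$parent, drop = FALSE]

up2_bwd <- function(dU, g_fine) {
  p <- g_fine$pool
  dU[, p[[1]], drop = FALSE] + dU[, p[[2]], drop = FALSE] +
    dU[, p[[3]], drop = FALSE] + dU[, p[[4]], drop = FALSE]
}

# Leaky activations keep a positive gradient everywhere (slope 0.1 on
# the negative side), which protects the small network from dying under
# the weak per-pixel gradients of the Jaccard loss.
lrelu_slope <- function(A) 0.1 + 0.9 * (A > 0)

softmax_cols <- function(z) {
  C <- nrow(z)
  mx <- z[1, ]
  for (i in 2:C) mx <- pmax(mx, z[i, ])
  e <- exp(z - matrix(mx, C, ncol(z), byrow = TRUE))
  e / matrix(colSums(e), C, ncol(z), byrow = TRUE)
}

#' Initialise the built-in tinyunet segmentation network
#'
#' He-normal initialisation on the current RNG stream (callers seed it).
#'
#' @param channels layer widths; see `TINYUNET_CHANNELS` defaults.
#' @return A named list of weight matrices and bias vectors with class
#'   `tinyunet`.
#' @export
init_tinyunet <- function(channels = TINYUNET_CHANNELS) {
  ch <- channels
  he <- function(cout, cin_k) matrix(rnorm(cout * cin_k, 0, sqrt(2 / cin_k)), cout, cin_k)
  params <- list(
    W1 = he(ch$enc1, 9 * 1), b1 = numeric(ch$enc1),
    W2 = he(ch$enc2, 9 * ch$enc1), b2 = numeric(ch$enc2),
    W3 = he(ch$bottleneck, 9 * ch$enc2), b3 = numeric(ch$bottleneck),
    W4 = he(ch$dec2, 9 * (ch$bottleneck + ch$enc2)), b4 = numeric(ch$dec2),
    W5 = he(ch$dec1, 9 * (ch$dec2 + ch$enc1)), b5 = numeric(ch$dec1),
    W6 = he(ch$classes, ch$dec1), b6 = numeric(ch$classes))
  structure(list(params = params, channels = ch), class = "tinyunet")
}

tinyunet_forward <- function(net, x_row, geom, keep = FALSE) {
  p <- net$params
  c1 <- conv3_fwd(x_row, p$W1, p$b1, geom$full)
  p1 <- pool2_fwd(c1, geom$full)
  c2 <- conv3_fwd(p1, p$W2, p$b2, geom$half)
  p2 <- pool2_fwd(c2, geom$half)
  c3 <- conv3_fwd(p2, p$W3, p$b3, geom$quarter)
  u2 <- up2_fwd(c3, geom$half)
  k2 <- rbind(u2, c2)
  d2 <- conv3_fwd(k2, p$W4, p$b4, geom$half)
  u1 <- up2_fwd(d2, geom$full)
  k1 <- rbind(u1, c1)
  d1 <- conv3_fwd(k1, p$W5, p$b5, geom$full)
  z <- p$W6 %*% d1 + p$b6
  probs <- softmax_cols(z)
  if (!keep) return(list(probs = probs))
  list(probs = probs, x = x_row, c1 = c1, p1 = p1, c2 = c2, p2 = p2,
       c3 = c3, k2 = k2, d2 = d2, k1 = k1, d1 = d1)
}

# Gradient of the Jaccard loss w.r.t. the logits, given softmax
# probabilities s and one-hot g (both C x N). Matches iou_loss() for
# either reduction.
iou_loss_grad_logits <- function(s, g, reduction = "pooled") {
  eps <- 1e-7
  if (reduction == "pooled") {
    inter <- sum(g * s) + eps
    uni <- sum(g + s - g * s) + eps
    dLds <- -(g * uni - inter * (1 - g)) / uni^2
  } else {
    inter_c <- rowSums(g * s) + eps
    uni_c <- rowSums(g + s - g * s) + eps
    dLds <- -(g * uni_c - inter_c * (1 - g)) / (uni_c^2 * nrow(s))
  }
  cs <- colSums(dLds * s)
  s * (dLds - matrix(cs, nrow(s), ncol(s), byrow = TRUE))
}

tinyunet_backward <- function(net, fwd, dz, geom) {
  p <- net$params
  g <- list()
  g$W6 <- dz %*% t(fwd$d1); g$b6 <- rowSums(dz)
  dd1 <- crossprod(p$W6, dz) * lrelu_slope(fwd$d1)
  bw5 <- conv3_bwd(fwd$k1, p$W5, dd1, geom$full)
  g$W5 <- bw5$dW; g$b5 <- bw5$db
  nb <- net$channels$dec2
  du1 <- bw5$dX[seq_len(nb), , drop = FALSE]
  dc1_skip <- bw5$dX[-seq_len(nb), , drop = FALSE]
  dd2 <- up2_bwd(du1, geom$full) * lrelu_slope(fwd$d2)
  bw4 <- conv3_bwd(fwd$k2, p$W4, dd2, geom$half)
  g$W4 <- bw4$dW; g$b4 <- bw4$db
  nbot <- net$channels$bottleneck
  du2 <- bw4$dX[seq_len(nbot), , drop = FALSE]
  dc2_skip <- bw4$dX[-seq_len(nbot), , drop = FALSE]
  dc3 <- up2_bwd(du2, geom$half) * lrelu_slope(fwd$c3)
  bw3 <- conv3_bwd(fwd$p2, p$W3, dc3, geom$quarter)
  g$W3 <- bw3$dW; g$b3 <- bw3$db
  dc2 <- (pool2_bwd(bw3$dX, geom$half) + dc2_skip) * lrelu_slope(fwd$c2)
  bw2 <- conv3_bwd(fwd$p1, p$W2, dc2, geom$half)
  g$W2 <- bw2$dW; g$b2 <- bw2$db
  dc1 <- (pool2_bwd(bw2$dX, geom$full) + dc1_skip) * lrelu_slope(fwd$c1)
  bw1 <- conv3_bwd(fwd$x, p$W1, dc1, geom$full, need_dX = FALSE)
  g$W1 <- bw1$dW; g$b1 <- bw1$db
  g
}

# Network input row: intensities centred at 0 (x - 0.5). Centring keeps
# early softmax outputs near-uniform, which the Jaccard loss needs to
# avoid saturating into confident wrong classes before features form.
input_row <- function(px) matrix(as.numeric(px) - 0.5, 1L)

# One-hot (C x N) encoding of a label map over classes 0..C-1.
one_hot_map <- function(map, C = 5L) {
  lab <- as.integer(unclass(map))
  g <- matrix(0, C, length(lab))
  g[cbind(lab + 1L, seq_along(lab))] <- 1
  g
}

#' Predict a five-class label map with a trained network
#'
#' Softmax probabilities are computed per pixel and the class with the
#' highest probability is taken, ties broken toward the lowest class
#' index.
#'
#' @param net a `tinyunet` (e.g. from [train_fold()]).
#' @param image an [octa_image()] or numeric matrix; side lengths must be
#'   divisible by 4.
#' @return A [label_map()].
#' @export
predict_label_map <- function(net, image) {
  px <- if (inherits(image, "octa_image")) image$pixels else image
  geom <- net_geometry(nrow(px), ncol(px))
  probs <- tinyunet_forward(net, input_row(px), geom)$probs
  cls <- max.col(t(probs), ties.method = "first") - 1L
  label_map(matrix(as.integer(cls), nrow(px), ncol(px)))
}

#' Resolve a segmentation model by name
#'
#' The harness treats the network as pluggable; the built-in small
#' encoder-decoder `"tinyunet"` is the only model shipped with the
#' package (large pretrained backbones are outside its scope).
#'
#' @param name model name.
#' @return An initialised model (weights drawn from the current RNG).
#' @export
model_factory <- function(name = "tinyunet") {
  if (!identical(name, "tinyunet"))
    stop(sprintf("unknown model '%s'; available: tinyunet", name),
         call. = FALSE)
  init_tinyunet()
}
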