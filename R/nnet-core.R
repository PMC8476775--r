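# Minimal dense/convolutional network engine used by the hybrid Bayesian
# network: im2col convolutions, 2x2 max pooling, global average pooling,
# dense layers with multiplicative Drop-Weights masks, sigmoid/BCE loss and
# an AMSGrad optimiser. Everything is plain R matrix algebra so training is
# exactly reproducible from one seed on a single thread.

he_uniform <- function(nrow, ncol, fan_in) {
  lim <- sqrt(6 / fan_in)
  matrix(stats::runif(nrow * ncol, -lim, lim), nrow, ncol)
}

#' Sample a Drop-Weights mask
#'
#' Independent Bernoulli(1 - rate) survival per weight; surviving weights are
#' scaled by `1/(1 - rate)` so the masked weight matrix is mean-preserving in
#' expectation. A rate of 0 returns the all-ones mask.
#'
#' @param shape Integer vector (dimensions of the weight tensor).
#' @param rate Drop probability in `[0, 1)`.
#' @return Array of the given shape with entries `0` or `1/(1 - rate)`.
#' @export
sample_drop_weights_mask <- function(shape, rate) {
  if (rate < 0 || rate >= 1) stop("rate must lie in [0, 1)", call. = FALSE)
  n <- prod(shape)
  if (rate == 0) return(array(1, shape))
  array((stats::runif(n) >= rate) / (1 - rate), shape)
}

# im2col index matrix for a 3x3 same-padded convolution on an
# side x side x cin input. Rows index output positions (column-major over the
# side x side grid), columns index the 27*cin patch entries in (dr, dc, ch)
# order. Indices refer to the zero-padded (side+2)^2 x cin array.
im2col_index <- function(side, cin, k = 3L) {
  sp <- side + k - 1L
  pos_r <- rep(seq_len(side), times = side)
  pos_c <- rep(seq_len(side), each = side)
  offs <- expand.grid(dr = 0:(k - 1L), dc = 0:(k - 1L), ch = 0:(cin - 1L))
  P <- side * side
  idx <- matrix(0L, P, k * k * cin)
  for (m in seq_len(nrow(offs))) {
    r <- pos_r + offs$dr[m]
    c <- pos_c + offs$dc[m]
    idx[, m] <- r + sp * (c - 1L) + sp * sp * offs$ch[m]
  }
  idx
}

pad_same <- function(x, k = 3L) {
  d <- dim(x)
  p <- (k - 1L) %/% 2L
  xp <- array(0, c(d[1] + 2L * p, d[2] + 2L * p, d[3]))
  xp[p + seq_len(d[1]), p + seq_len(d[2]), ] <- x
  xp
}

layer_idx <- function(layer, cin) {
  # large backbones skip the build-time cache (the index matrix scales with
  # side^2 * 9 * cin) and gather patches on demand
  layer$idx %||% im2col_index(layer$side, cin)
}

conv_forward <- function(x, layer) {
  xp <- pad_same(x)
  idx <- layer_idx(layer, dim(x)[3])
  X2 <- matrix(xp[idx], nrow(idx), ncol(idx))
  Z <- X2 %*% layer$W
  Z <- sweep(Z, 2, layer$b, "+")
  A <- pmax(Z, 0)
  list(
    out = array(A, c(layer$side, layer$side, ncol(layer$W))),
    cache = list(X2 = X2, relu = Z > 0, dim_in = dim(x))
  )
}

conv_backward <- function(dout, layer, cache) {
  idx <- layer_idx(layer, cache$dim_in[3])
  P <- nrow(idx)
  dZ <- matrix(dout, P, ncol(layer$W)) * cache$relu
  dW <- crossprod(cache$X2, dZ)
  db <- colSums(dZ)
  dX2 <- dZ %*% t(layer$W)
  sp <- layer$side + 2L
  dxp <- numeric(sp * sp * cache$dim_in[3])
  # scatter-add column-wise: within one patch-offset column every padded
  # position is referenced at most once, so plain indexed addition is exact
  for (m in seq_len(ncol(idx))) {
    ix <- idx[, m]
    dxp[ix] <- dxp[ix] + dX2[, m]
  }
  dxp <- array(dxp, c(sp, sp, cache$dim_in[3]))
  dx <- dxp[2:(layer$side + 1L), 2:(layer$side + 1L), , drop = FALSE]
  list(dx = dx, dW = dW, db = db)
}

maxpool_forward <- function(x) {
  d <- dim(x)
  o1 <- seq(1L, d[1], 2L)
  o2 <- seq(1L, d[2], 2L)
  a <- x[o1, o2, , drop = FALSE]
  b <- x[o1, o2 + 1L, , drop = FALSE]
  cc <- x[o1 + 1L, o2, , drop = FALSE]
  dd <- x[o1 + 1L, o2 + 1L, , drop = FALSE]
  out <- pmax(a, b, cc, dd)
  list(out = out, cache = list(x = x, out = out))
}

maxpool_backward <- function(dout, cache) {
  x <- cache$x
  d <- dim(x)
  o1 <- seq(1L, d[1], 2L)
  o2 <- seq(1L, d[2], 2L)
  out <- cache$out
  m <- list(
    x[o1, o2, , drop = FALSE] == out,
    x[o1, o2 + 1L, , drop = FALSE] == out,
    x[o1 + 1L, o2, , drop = FALSE] == out,
    x[o1 + 1L, o2 + 1L, , drop = FALSE] == out
  )
  cnt <- m[[1]] + m[[2]] + m[[3]] + m[[4]]
  g <- dout / cnt
  dx <- array(0, d)
  dx[o1, o2, ] <- m[[1]] * g
  dx[o1, o2 + 1L, ] <- m[[2]] * g
  dx[o1 + 1L, o2, ] <- m[[3]] * g
  dx[o1 + 1L, o2 + 1L, ] <- m[[4]] * g
  dx
}

dense_forward <- function(X, W, b, mask = NULL, relu = TRUE) {
  Wm <- if (is.null(mask)) W else W * mask
  Z <- X %*% Wm
  Z <- sweep(Z, 2, b, "+")
  A <- if (relu) pmax(Z, 0) else Z
  list(out = A, cache = list(X = X, Wm = Wm, mask = mask, relu_mask = if (relu) Z > 0 else NULL))
}

dense_backward <- function(dout, W, cache) {
  dZ <- if (is.null(cache$relu_mask)) dout else dout * cache$relu_mask
  dWm <- crossprod(cache$X, dZ)
  dW <- if (is.null(cache$mask)) dWm else dWm * cache$mask
  db <- colSums(dZ)
  dX <- dZ %*% t(cache$Wm)
  list(dx = dX, dW = dW, db = db)
}

sigmoid <- function(z) 1 / (1 + exp(-z))

# Mean binary cross-entropy over all (sample, label) cells, with probability
# clipping for numerical safety; gradient returned w.r.t. the pre-sigmoid
# logits.
bce_loss <- function(P, Y, eps = 1e-12) {
  Pc <- pmin(pmax(P, eps), 1 - eps)
  loss <- -mean(Y * log(Pc) + (1 - Y) * log(1 - Pc))
  dZ <- (P - Y) / length(Y)
  list(loss = loss, dZ = dZ)
}

# AMSGrad: adaptive-moment update with the maximum-of-past-second-moment
# correction. State is kept per parameter tensor.
amsgrad_init <- function(param) {
  list(m = param * 0, v = param * 0, vhat = param * 0, t = 0L)
}

amsgrad_step <- function(param, grad, state, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- beta1 * state$m + (1 - beta1) * grad
  state$v <- beta2 * state$v + (1 - beta2) * grad^2
  state$vhat <- pmax(state$vhat, state$v)
  mhat <- state$m / (1 - beta1^state$t)
  param <- param - lr * mhat / (sqrt(state$vhat) + eps)
  list(param = param, state = state)
}
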