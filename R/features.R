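#' Histogram of oriented gradients
#'
#' HOG descriptor with unsigned gradient orientations binned over
#' `[0, 180)` degrees, square cells of `cell_px` pixels, blocks of
#' `cells_per_block x cells_per_block` cells with a stride of one cell, and
#' per-block L2 normalisation. With the defaults (8 orientation bins, 8 px
#' cells, 8 x 8 cells per block) a 64 x 64 image yields a single block and a
#' 512-long descriptor.
#'
#' @param gray `H x W` numeric matrix (luminance image).
#' @param orientations Number of orientation bins over `[0, 180)`.
#' @param cell_px Cell side in pixels; both image sides must be divisible by it.
#' @param cells_per_block Cells per block side.
#' @return Numeric vector of length
#'   `nblocks_y * nblocks_x * cells_per_block^2 * orientations`.
#' @export
hog_features <- function(gray, orientations = 8L, cell_px = 8L, cells_per_block = 8L) {
  d <- dim(gray)
  if (is.null(d) || length(d) != 2L) stop("gray must be a 2-D matrix", call. = FALSE)
  if (any(d %% cell_px != 0L)) {
    stop("image sides must be divisible by cell_px = ", cell_px, call. = FALSE)
  }
  ncy <- d[1] %/% cell_px
  ncx <- d[2] %/% cell_px
  if (min(ncy, ncx) < cells_per_block) {
    stop("image smaller than one block (need >= ", cells_per_block,
      " cells per side, have ", min(ncy, ncx), ")",
      call. = FALSE
    )
  }
  # central-difference gradients with edge replication
  gx <- (gray[, c(2:d[2], d[2])] - gray[, c(1, 1:(d[2] - 1))]) / 2
  gy <- (gray[c(2:d[1], d[1]), ] - gray[c(1, 1:(d[1] - 1)), ]) / 2
  mag <- sqrt(gx^2 + gy^2)
  ang <- atan2(gy, gx) * 180 / pi # (-180, 180]
  ang <- ang %% 180 # unsigned, [0, 180)
  bin <- pmin(floor(ang / (180 / orientations)), orientations - 1)
  # accumulate magnitude per (cell, bin)
  cy <- (row(gray) - 1L) %/% cell_px
  cx <- (col(gray) - 1L) %/% cell_px
  idx <- 1L + bin + orientations * (cy + ncy * cx)
  hist_flat <- numeric(orientations * ncy * ncx)
  acc <- rowsum(as.vector(mag), group = as.vector(idx))
  hist_flat[as.integer(rownames(acc))] <- acc[, 1]
  H <- array(hist_flat, c(orientations, ncy, ncx))
  nby <- ncy - cells_per_block + 1L
  nbx <- ncx - cells_per_block + 1L
  out <- numeric(nby * nbx * cells_per_block^2 * orientations)
  blen <- cells_per_block^2 * orientations
  k <- 0L
  for (bx in seq_len(nbx)) {
    for (by in seq_len(nby)) {
      blk <- H[, by:(by + cells_per_block - 1L), bx:(bx + cells_per_block - 1L)]
      nrm <- sqrt(sum(blk^2))
      if (nrm > 0) blk <- blk / nrm
      out[(k * blen + 1L):((k + 1L) * blen)] <- blk
      k <- k + 1L
    }
  }
  out
}

# Symmetric normalised grey-level co-occurrence matrix for one offset.
glcm <- function(q, levels, dy, dx) {
  d <- dim(q)
  r1 <- seq_len(d[1] - abs(dy))
  c1 <- seq_len(d[2] - abs(dx))
  if (dy < 0) r1 <- r1 + abs(dy)
  if (dx < 0) c1 <- c1 + abs(dx)
  a <- q[cbind(
    rep(r1, times = length(c1)),
    rep(c1, each = length(r1))
  )]
  b <- q[cbind(
    rep(r1 + dy, times = length(c1)),
    rep(c1 + dx, each = length(r1))
  )]
  counts <- tabulate(a * levels + b + 1L, nbins = levels^2)
  P <- matrix(counts, levels, levels, byrow = TRUE)
  P <- P + t(P)
  P / sum(P)
}

haralick_one <- function(P) {
  levels <- nrow(P)
  i <- row(P) - 1
  j <- col(P) - 1
  px <- rowSums(P)
  py <- colSums(P)
  mu_x <- sum((0:(levels - 1)) * px)
  mu_y <- sum((0:(levels - 1)) * py)
  s_x <- sqrt(sum(((0:(levels - 1)) - mu_x)^2 * px))
  s_y <- sqrt(sum(((0:(levels - 1)) - mu_y)^2 * py))
  # p_{x+y}(k), k = 0..2(levels-1); p_{x-y}(k), k = 0..levels-1
  pxy_sum <- rowsum(as.vector(P), group = as.vector(i + j))[, 1]
  k_sum <- sort(unique(as.vector(i + j)))
  pxy_diff <- rowsum(as.vector(P), group = as.vector(abs(i - j)))[, 1]
  k_diff <- sort(unique(as.vector(abs(i - j))))
  xlogx <- function(p) ifelse(p > 0, p * log2(p), 0)
  asm <- sum(P^2)
  contrast <- sum((i - j)^2 * P)
  correlation <- if (s_x * s_y > 0) sum((i - mu_x) * (j - mu_y) * P) / (s_x * s_y) else 0
  variance <- sum((i - mu_x)^2 * P)
  idm <- sum(P / (1 + (i - j)^2))
  sum_average <- sum(k_sum * pxy_sum)
  sum_entropy <- -sum(xlogx(pxy_sum))
  sum_variance <- sum((k_sum - sum_average)^2 * pxy_sum)
  entropy <- -sum(xlogx(P))
  diff_average <- sum(k_diff * pxy_diff)
  diff_variance <- sum((k_diff - diff_average)^2 * pxy_diff)
  diff_entropy <- -sum(xlogx(pxy_diff))
  hxy <- entropy
  hx <- -sum(xlogx(px))
  hy <- -sum(xlogx(py))
  pxpy <- outer(px, py)
  hxy1 <- -sum(P * ifelse(pxpy > 0, log2(pxpy), 0))
  hxy2 <- -sum(xlogx(pxpy))
  imc1 <- if (max(hx, hy) > 0) (hxy - hxy1) / max(hx, hy) else 0
  imc2 <- sqrt(pmax(1 - exp(-2 * log(2) * (hxy2 - hxy)), 0))
  c(
    asm = asm, contrast = contrast, correlation = correlation,
    variance = variance, idm = idm, sum_average = sum_average,
    sum_variance = sum_variance, sum_entropy = sum_entropy,
    entropy = entropy, diff_variance = diff_variance,
    diff_entropy = diff_entropy, imc1 = imc1, imc2 = imc2
  )
}

#' Haralick texture features
#'
#' The 13 classical co-occurrence statistics (angular second moment,
#' contrast, correlation, sum of squares variance, inverse difference
#' moment, sum average, sum variance, sum entropy, entropy, difference
#' variance, difference entropy, and the two information measures of
#' correlation), computed on symmetric, normalised co-occurrence matrices and
#' averaged over the four offsets 0, 45, 90 and 135 degrees. The correlation
#' feature of a zero-variance (single-valued) image is defined as 0 so the
#' output is always finite.
#'
#' @param gray `H x W` numeric matrix with values in 0..255.
#' @param levels Number of grey levels for quantisation.
#' @param distance Co-occurrence offset in pixels.
#' @param directions Angles (degrees) to average over.
#' @return Named numeric vector of length 13.
#' @export
haralick_features <- function(gray, levels = 256L, distance = 1L,
                              directions = c(0, 45, 90, 135)) {
  d <- dim(gray)
  if (is.null(d) || any(d < 2L)) stop("image must be at least 2 x 2", call. = FALSE)
  q <- pmin(pmax(floor(gray / 256 * levels), 0), levels - 1)
  storage.mode(q) <- "integer"
  offs <- list(
    `0` = c(0L, 1L), `45` = c(-1L, 1L), `90` = c(-1L, 0L), `135` = c(-1L, -1L)
  )
  feats <- vapply(
    as.character(directions),
    function(a) {
      o <- offs[[a]] * distance
      haralick_one(glcm(q, levels, o[1], o[2]))
    },
    numeric(13)
  )
  rowMeans(feats)
}

#' Hu invariant moments
#'
#' The seven Hu moment invariants of the intensity image, made numerically
#' comparable by the signed log transform `sign(h) * log10(|h|)` (0 maps
#' to 0). An all-zero image returns the zero vector by convention.
#'
#' @param gray `H x W` numeric matrix.
#' @return Numeric vector of length 7.
#' @export
hu_moments <- function(gray) {
  d <- dim(gray)
  if (is.null(d) || any(d < 1L)) stop("image must be non-empty", call. = FALSE)
  m00 <- sum(gray)
  if (m00 == 0) return(numeric(7))
  x <- col(gray) - 1
  y <- row(gray) - 1
  xb <- sum(x * gray) / m00
  yb <- sum(y * gray) / m00
  mu <- function(p, q) sum((x - xb)^p * (y - yb)^q * gray)
  eta <- function(p, q) mu(p, q) / m00^(1 + (p + q) / 2)
  n20 <- eta(2, 0); n02 <- eta(0, 2); n11 <- eta(1, 1)
  n30 <- eta(3, 0); n03 <- eta(0, 3); n21 <- eta(2, 1); n12 <- eta(1, 2)
  h <- numeric(7)
  h[1] <- n20 + n02
  h[2] <- (n20 - n02)^2 + 4 * n11^2
  h[3] <- (n30 - 3 * n12)^2 + (3 * n21 - n03)^2
  h[4] <- (n30 + n12)^2 + (n21 + n03)^2
  h[5] <- (n30 - 3 * n12) * (n30 + n12) * ((n30 + n12)^2 - 3 * (n21 + n03)^2) +
    (3 * n21 - n03) * (n21 + n03) * (3 * (n30 + n12)^2 - (n21 + n03)^2)
  h[6] <- (n20 - n02) * ((n30 + n12)^2 - (n21 + n03)^2) +
    4 * n11 * (n30 + n12) * (n21 + n03)
  h[7] <- (3 * n21 - n03) * (n30 + n12) * ((n30 + n12)^2 - 3 * (n21 + n03)^2) -
    (n30 - 3 * n12) * (n21 + n03) * (3 * (n30 + n12)^2 - (n21 + n03)^2)
  ifelse(h == 0, 0, sign(h) * log10(abs(h)))
}

#' Fit / apply a PCA reduction of the handcrafted block
#'
#' `fit_pca()` centres the feature matrix and keeps the top `target_dim`
#' principal axes ordered by decreasing variance; `apply_pca()` projects new
#' vectors into that subspace. Components are orthonormal.
#'
#' @param X `n x d` numeric matrix (rows = images).
#' @param target_dim Number of components; must satisfy
#'   `target_dim <= min(n - 1, d)`.
#' @return `fit_pca()`: a list with class `"ihc_pca"` holding `center`
#'   (length-d mean), `components` (`target_dim x d`, orthonormal rows) and
#'   `variance` (per-component variance fractions). `apply_pca()`: an
#'   `m x target_dim` matrix (or vector for a single input vector).
#' @export
fit_pca <- function(X, target_dim) {
  X <- as.matrix(X)
  n <- nrow(X)
  d <- ncol(X)
  if (n < 2L) stop("PCA needs at least 2 rows", call. = FALSE)
  kmax <- min(n - 1L, d)
  if (target_dim > kmax) {
    stop("target_dim = ", target_dim, " too large; admissible maximum is ",
      kmax, " for a ", n, " x ", d, " matrix",
      call. = FALSE
    )
  }
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE, rank. = target_dim)
  ev <- pc$sdev^2
  structure(
    list(
      center = pc$center,
      components = t(pc$rotation[, seq_len(target_dim), drop = FALSE]),
      variance = ev[seq_len(target_dim)] / sum(ev)
    ),
    class = "ihc_pca"
  )
}

#' @rdname fit_pca
#' @param model A fitted `"ihc_pca"`.
#' @param x A single vector of length d or an `m x d` matrix.
#' @export
apply_pca <- function(model, x) {
  stopifnot(inherits(model, "ihc_pca"))
  single <- is.null(dim(x))
  X <- if (single) matrix(x, nrow = 1) else as.matrix(x)
  Z <- sweep(X, 2, model$center) %*% t(model$components)
  if (single) drop(Z) else Z
}

#' Clamp a requested PCA dimensionality to what the data admit
#'
#' The reference workflow reduces the handcrafted block to 3732 components,
#' which is only reachable at full-dataset scale; small runs clamp to
#' `min(n - 1, d)` with a warning.
#'
#' @inheritParams fit_pca
#' @return Integer.
#' @export
clamp_pca_dim <- function(target_dim, X) {
  kmax <- min(nrow(X) - 1L, ncol(X))
  if (target_dim > kmax) {
    warning("PCA target_dim clamped from ", target_dim, " to ", kmax, call. = FALSE)
    return(as.integer(kmax))
  }
  as.integer(target_dim)
}

#' Feature standardiser (z-score on training statistics)
#'
#' HOG, Haralick and Hu features live on very different scales; each feature
#' is centred and scaled by training-set mean and standard deviation before
#' PCA (features with zero spread are left unscaled).
#'
#' @param X Training `n x d` matrix.
#' @return A list with class `"ihc_scaler"`.
#' @export
fit_scaler <- function(X) {
  X <- as.matrix(X)
  mu <- colMeans(X)
  sd <- apply(X, 2, stats::sd)
  sd[!is.finite(sd) | sd == 0] <- 1
  structure(list(mean = mu, sd = sd), class = "ihc_scaler")
}

#' @rdname fit_scaler
#' @param scaler A fitted `"ihc_scaler"`.
#' @param x Vector or matrix to standardise.
#' @export
apply_scaler <- function(scaler, x) {
  single <- is.null(dim(x))
  X <- if (single) matrix(x, nrow = 1) else as.matrix(x)
  Z <- sweep(sweep(X, 2, scaler$mean), 2, scaler$sd, "/")
  if (single) drop(Z) else Z
}

#' Concatenate CNN and handcrafted features into the hybrid vector
#'
#' CNN features come first, the PCA-reduced handcrafted block second.
#'
#' @param cnn Numeric vector of learned features.
#' @param handcrafted Numeric vector of reduced handcrafted features (may be
#'   empty for a CNN-only ablation).
#' @return Numeric vector of length `length(cnn) + length(handcrafted)`.
#' @export
assemble_hybrid <- function(cnn, handcrafted) {
  out <- c(as.numeric(cnn), as.numeric(handcrafted))
  if (!all(is.finite(out))) stop("hybrid feature vector contains non-finite values", call. = FALSE)
  out
}

#' Handcrafted descriptor vector for one image
#'
#' Luminance conversion followed by HOG, Haralick and Hu extraction and
#' concatenation (in that order).
#'
#' @param pixels `H x W x 3` array, values 0..255.
#' @param hog_opts,haralick_opts Optional argument lists passed on.
#' @return Numeric vector.
#' @export
handcrafted_features <- function(pixels, hog_opts = list(), haralick_opts = list()) {
  gray <- rgb_to_gray(pixels)
  c(
    do.call(hog_features, c(list(gray), hog_opts)),
    do.call(haralick_features, c(list(gray), haralick_opts)),
    hu_moments(gray)
  )
}

#' Handcrafted feature matrix for a set of images
#'
#' @param images Named list of `H x W x 3` arrays (names = image ids).
#' @param ... Passed to [handcrafted_features()].
#' @return `n x d` matrix with image ids as rownames.
#' @export
handcrafted_matrix <- function(images, ...) {
  feats <- lapply(images, handcrafted_features, ...)
  X <- do.call(rbind, feats)
  rownames(X) <- names(images)
  X
}
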