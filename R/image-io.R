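#' Load an RGB image as an 8-bit array
#'
#' Reads JPEG, PNG or TIFF into an `H x W x 3` integer array with values in
#' 0..255. Grayscale inputs are replicated across channels, alpha channels are
#' dropped, and 16-bit inputs are linearly rescaled to 8 bits with a warning.
#'
#' @param path Path to an image file (extension decides the decoder; JPEG
#'   requires the EBImage package).
#' @return `H x W x 3` integer array.
#' @export
load_image <- function(path) {
  if (!file.exists(path)) stop("image file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path, as.is = TRUE),
    jpg = ,
    jpeg = {
      if (!requireNamespace("EBImage", quietly = TRUE)) {
        stop("JPEG decoding requires the EBImage package", call. = FALSE)
      }
      img <- EBImage::readImage(path)
      aperm(EBImage::imageData(img), if (length(dim(img)) == 3L) c(2, 1, 3) else c(2, 1))
    },
    stop("not a supported image format: .", ext, call. = FALSE)
  )
  if (is.null(dim(px)) || length(dim(px)) < 2L) {
    stop("file did not decode to an image: ", path, call. = FALSE)
  }
  # readPNG/readImage return [0,1] doubles; readTIFF(as.is) returns integers
  if (is.double(px) && max(px) <= 1 + 1e-9) px <- px * 255
  if (max(px) > 255) {
    warning("rescaling >8-bit image to 8-bit range", call. = FALSE)
    px <- px / max(px) * 255
  }
  if (length(dim(px)) == 2L) px <- array(px, c(dim(px), 1L))
  if (dim(px)[3] == 1L) px <- px[, , c(1L, 1L, 1L), drop = FALSE]
  if (dim(px)[3] > 3L) px <- px[, , 1:3, drop = FALSE]
  storage.mode(px) <- "integer"
  pmax(pmin(px, 255L), 0L)
}

#' Save an 8-bit RGB array as PNG
#'
#' @param pixels `H x W x 3` array, values 0..255.
#' @param path Output path (`.png`).
#' @return `path`, invisibly.
#' @export
save_image <- function(pixels, path) {
  check_pixels(pixels)
  png::writePNG(pixels / 255, path)
  invisible(path)
}

check_pixels <- function(pixels) {
  d <- dim(pixels)
  if (length(d) != 3L || d[3] != 3L) stop("pixels must be an H x W x 3 array", call. = FALSE)
  if (d[1] < 32L || d[2] < 32L) stop("image sides must be at least 32 pixels", call. = FALSE)
  invisible(pixels)
}

# Catmull-Rom cubic convolution kernel (a = -0.5), the classical bicubic
# interpolation over a 4x4 neighbourhood.
cubic_kernel <- function(x, a = -0.5) {
  x <- abs(x)
  ifelse(x <= 1, (a + 2) * x^3 - (a + 3) * x^2 + 1,
    ifelse(x < 2, a * x^3 - 5 * a * x^2 + 8 * a * x - 4 * a, 0)
  )
}

# n_out x n_in interpolation matrix mapping source samples to target samples
# under pixel-centre alignment; border samples are edge-clamped.
bicubic_matrix <- function(n_in, n_out) {
  if (n_in == n_out) return(diag(n_in))
  scale <- n_in / n_out
  u <- (seq_len(n_out) - 0.5) * scale + 0.5 # source coordinate, 1-based
  i0 <- floor(u - 2) + 1
  M <- matrix(0, n_out, n_in)
  for (k in 0:3) {
    idx <- i0 + k
    w <- cubic_kernel(u - idx)
    idx <- pmax(pmin(idx, n_in), 1)
    M[cbind(seq_len(n_out), idx)] <- M[cbind(seq_len(n_out), idx)] + w
  }
  M / rowSums(M)
}

#' Resize an image with bicubic interpolation
#'
#' Separable cubic-convolution resampling over a 4 x 4 source neighbourhood
#' (Catmull-Rom kernel), the interpolation used to bring the 3000 x 3000
#' source crops down to the network input size. Output values are clipped to
#' 0..255. Resizing to the current size is the identity.
#'
#' @param pixels `H x W x 3` array (or `H x W` matrix), values 0..255.
#' @param side Target side in pixels (>= 32); output is `side x side`.
#' @return Resized array of the same kind as the input.
#' @export
resize_image <- function(pixels, side) {
  side <- as.integer(side)
  if (side < 32L) stop("target side must be at least 32", call. = FALSE)
  d <- dim(pixels)
  is2d <- length(d) == 2L
  if (is2d) pixels <- array(pixels, c(d, 1L))
  d <- dim(pixels)
  Ry <- bicubic_matrix(d[1], side)
  Rx <- bicubic_matrix(d[2], side)
  out <- array(0, c(side, side, d[3]))
  for (ch in seq_len(d[3])) {
    out[, , ch] <- Ry %*% pixels[, , ch] %*% t(Rx)
  }
  out <- pmax(pmin(out, 255), 0)
  if (is2d) out[, , 1] else out
}

#' Convert an RGB array to luminance grayscale
#'
#' Uses the Rec. 709 luminance weights 0.2125 R + 0.7154 G + 0.0721 B. All
#' handcrafted descriptors are computed on this channel.
#'
#' @param pixels `H x W x 3` array, values 0..255.
#' @return `H x W` double matrix in 0..255.
#' @export
rgb_to_gray <- function(pixels) {
  d <- dim(pixels)
  if (length(d) != 3L || d[3] != 3L) stop("pixels must be an H x W x 3 array", call. = FALSE)
  0.2125 * pixels[, , 1] + 0.7154 * pixels[, , 2] + 0.0721 * pixels[, , 3]
}
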