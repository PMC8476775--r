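test_that("HOG descriptor length follows the block arithmetic", {
  g64 <- matrix(runif(64 * 64, 0, 255), 64)
  expect_length(hog_features(g64), 512) # 1 block x 64 cells x 8 bins
  g128 <- matrix(runif(128 * 128, 0, 255), 128)
  expect_length(hog_features(g128), 41472) # 9 x 9 blocks x 512
  # property: random admissible sizes
  set.seed(7)
  for (i in 1:5) {
    nc <- sample(8:14, 1)
    g <- matrix(runif((8 * nc)^2, 0, 255), 8 * nc)
    nb <- nc - 8 + 1
    expect_length(hog_features(g), nb^2 * 64 * 8)
  }
})

test_that("HOG of a constant image is all zero and blocks are L2-normalised", {
  expect_true(all(hog_features(matrix(5, 64, 64)) == 0))
  g <- matrix(runif(64 * 64, 0, 255), 64)
  v <- hog_features(g)
  expect_equal(sum(v^2), 1, tolerance = 1e-9) # single block
})

test_that("HOG rejects images smaller than one block or not cell-divisible", {
  expect_error(hog_features(matrix(0, 32, 32)), "smaller than one block")
  expect_error(hog_features(matrix(0, 60, 60)), "divisible")
})

test_that("Haralick features are 13 finite direction-averaged statistics", {
  g <- matrix(runif(32 * 32, 0, 255), 32)
  f <- haralick_features(g)
  expect_length(f, 13)
  expect_true(all(is.finite(f)))
  # transpose symmetry of the direction-averaged output
  expect_equal(haralick_features(t(g)), f, tolerance = 1e-10)
})

test_that("Haralick degenerate and hand-computed cases", {
  # constant image: all co-occurrence mass in one cell
  f <- haralick_features(matrix(17, 16, 16))
  expect_equal(unname(f["asm"]), 1)
  expect_equal(unname(f["contrast"]), 0)
  expect_equal(unname(f["correlation"]), 0) # zero-variance convention
  expect_true(all(is.finite(f)))
  # checkerboard of 0/255 at distance 1, 0 degrees: every horizontal
  # neighbour pair differs by 255 grey levels
  cb <- 255 * outer(1:8, 1:8, function(i, j) (i + j) %% 2)
  f0 <- haralick_features(cb, directions = 0)
  expect_equal(unname(f0["contrast"]), 255^2)
  expect_equal(unname(f0["asm"]), 0.5)
})

test_that("Hu moments are translation and rotation invariant and log-scaled", {
  set.seed(11)
  blob <- matrix(0, 64, 64)
  blob[20:33, 14:30] <- matrix(runif(14 * 17, 50, 255), 14)
  shifted <- matrix(0, 64, 64)
  shifted[28:41, 30:46] <- blob[20:33, 14:30]
  h0 <- hu_moments(blob)
  expect_equal(hu_moments(shifted), h0, tolerance = 1e-6)
  rotated <- t(blob)[64:1, ] # 90-degree rotation
  expect_equal(hu_moments(rotated), h0, tolerance = 1e-4)
  expect_identical(hu_moments(matrix(0, 8, 8)), numeric(7))
})

test_that("PCA recovers exact low-rank structure and conserves variance", {
  set.seed(5)
  # points on a 2-D plane embedded in 10-D
  B <- matrix(rnorm(20), 10, 2)
  Z <- matrix(rnorm(60), 30, 2)
  X <- Z %*% t(B)
  pca <- fit_pca(X, 2)
  rec <- apply_pca(pca, X) %*% pca$components
  rec <- sweep(rec, 2, pca$center, "+")
  expect_lt(max(abs(rec - X)), 1e-8)
  # projecting the training mean gives the zero vector
  expect_equal(unname(apply_pca(pca, colMeans(X))), c(0, 0), tolerance = 1e-10)
  # full-rank projection conserves total variance
  X2 <- matrix(rnorm(1000), 50, 20)
  pca2 <- fit_pca(X2, 20)
  Z2 <- apply_pca(pca2, X2)
  expect_equal(sum(apply(Z2, 2, var)), sum(apply(X2, 2, var)), tolerance = 1e-6)
  # components orthonormal, variance non-increasing
  G <- pca2$components %*% t(pca2$components)
  expect_lt(max(abs(G - diag(20))), 1e-6)
  expect_true(all(diff(apply(Z2, 2, var)) < 1e-9))
})

test_that("PCA rejects an inadmissible target dimension, and clamping warns", {
  X <- matrix(rnorm(50), 5, 10)
  expect_error(fit_pca(X, 5), "admissible maximum is 4")
  expect_warning(k <- clamp_pca_dim(3732, X), "clamped")
  expect_identical(k, 4L)
})

test_that("hybrid assembly concatenates CNN features first", {
  cnn <- rnorm(256)
  hand <- rnorm(37)
  h <- assemble_hybrid(cnn, hand)
  expect_length(h, 293)
  expect_identical(h[1:256], cnn)
  expect_identical(assemble_hybrid(cnn, numeric(0)), cnn)
  expect_error(assemble_hybrid(c(1, NA), hand), "non-finite")
})

test_that("feature standardisation uses training statistics", {
  set.seed(2)
  X <- cbind(rnorm(40, 5, 2), rnorm(40, -3, 0.5), rep(7, 40))
  sc <- fit_scaler(X)
  Z <- apply_scaler(sc, X)
  expect_equal(colMeans(Z), c(0, 0, 0), tolerance = 1e-12)
  expect_equal(unname(apply(Z[, 1:2], 2, sd)), c(1, 1), tolerance = 1e-12)
  expect_true(all(is.finite(Z))) # constant feature left unscaled
})
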