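# a tiny network used throughout: 32 px input keeps every test fast
tiny_cfg <- function(...) {
  hbnet_profile("desk",
    input_side = 32L, cnn_feature_dim = 8L,
    fc_layer_sizes = c(12L), ...
  )
}

test_that("configuration validates its invariants and profiles override them", {
  expect_error(hbnet_config(drop_weight_rate = 1), "\\[0, 1\\)")
  expect_error(hbnet_config(n_labels = 0), ">= 1")
  ref <- hbnet_config()
  expect_equal(ref$learning_rate, 1e-6)
  expect_equal(ref$epochs, 250L)
  expect_equal(ref$weight_decay, 0.2)
  expect_equal(ref$batch_size, 32L)
  expect_equal(ref$drop_weight_rate, 0.3)
  desk <- hbnet_profile("desk")
  expect_equal(desk$backbone, "small_cnn")
  expect_equal(desk$input_side, 64L)
  full <- hbnet_profile("paper_scale")
  expect_equal(full$backbone, "vgg19_like")
  expect_equal(full$input_side, 1024L)
  expect_length(ihctriage:::trunk_channels("vgg19_like") |> unlist(), 16L)
})

test_that("the reference-scale backbone is constructible with pooled projection", {
  m <- build_hbnet(hbnet_config(backbone = "vgg19_like", seed = 1), handcrafted_dim = 3732L)
  expect_length(m$trunk, 16L)
  expect_identical(dim(m$trunk[[1]]$W), c(27L, 64L))
  expect_identical(dim(m$trunk[[16]]$W), c(4608L, 512L))
  expect_identical(m$pool_mode, "gap")
  expect_identical(dim(m$proj$W), c(512L, 256L))
  # head accepts the 256 + 3732 hybrid vector
  expect_identical(nrow(m$head[[1]]$W), 3988L)
  rm(m)
})

test_that("drop-weights masks honour rate, scaling and the mean-preserving property", {
  set.seed(41)
  expect_true(all(sample_drop_weights_mask(c(10, 10), 0) == 1))
  m <- sample_drop_weights_mask(c(100, 100), 0.3)
  expect_true(all(m %in% c(0, 1 / 0.7)))
  frac <- mean(m == 0)
  expect_gt(frac, 0.28)
  expect_lt(frac, 0.32)
  # law of large numbers: the masked weight is unbiased
  w <- 1.7
  draws <- replicate(1e4, w * sample_drop_weights_mask(1L, 0.3))
  expect_equal(mean(draws), w, tolerance = 0.02)
  expect_error(sample_drop_weights_mask(c(2, 2), 1), "\\[0, 1\\)")
})

test_that("built model maps an image to sigmoid outputs with the expected stochasticity", {
  set.seed(42)
  img <- toy_image(32)
  m0 <- build_hbnet(tiny_cfg(drop_weight_rate = 0, seed = 2), handcrafted_dim = 0L)
  p1 <- hbnet_forward(m0, img, stochastic = TRUE)
  p2 <- hbnet_forward(m0, img, stochastic = TRUE)
  expect_length(p1, 8)
  expect_true(all(p1 > 0 & p1 < 1))
  expect_identical(p1, p2) # rate 0: no stochasticity
  m3 <- build_hbnet(tiny_cfg(drop_weight_rate = 0.3, seed = 2), handcrafted_dim = 0L)
  q1 <- hbnet_forward(m3, img, stochastic = TRUE)
  q2 <- hbnet_forward(m3, img, stochastic = TRUE)
  expect_false(identical(q1, q2))
  expect_error(hbnet_forward(m3, img, handcrafted = rnorm(5)), "length 0")
})

test_that("analytic gradients match finite differences through conv, pool and head", {
  set.seed(43)
  cfg <- tiny_cfg(drop_weight_rate = 0, seed = 3)
  m <- build_hbnet(cfg, handcrafted_dim = 4L)
  img <- ihctriage:::prep_input(toy_image(32, seed = 5))
  hand <- rnorm(4)
  y <- matrix(rbinom(8, 1, 0.5), 1)
  loss_of <- function(m) {
    tf <- ihctriage:::trunk_forward(m, img)
    hf <- ihctriage:::head_forward(m, matrix(c(tf$cnn, hand), 1))
    ihctriage:::bce_loss(hf$probs, y)$loss
  }
  tf <- ihctriage:::trunk_forward(m, img, keep_cache = TRUE)
  hf <- ihctriage:::head_forward(m, matrix(c(tf$cnn, hand), 1), keep_cache = TRUE)
  lb <- ihctriage:::bce_loss(hf$probs, y)
  hb <- ihctriage:::head_backward(m, lb$dZ, hf$cache)
  tb <- ihctriage:::trunk_backward(m, hb$dhybrid[, 1:8], tf$cache)
  eps <- 1e-6
  check_tensor <- function(getter, setter, analytic, k = 4) {
    idx <- sample(length(getter(m)), k)
    for (i in idx) {
      mp <- m
      v <- getter(mp)
      v[i] <- v[i] + eps
      mp <- setter(mp, v)
      mm <- m
      v <- getter(mm)
      v[i] <- v[i] - eps
      mm <- setter(mm, v)
      num <- (loss_of(mp) - loss_of(mm)) / (2 * eps)
      expect_equal(analytic[i], num, tolerance = 1e-4)
    }
  }
  check_tensor(
    function(m) m$trunk[[1]]$W,
    function(m, v) {
      m$trunk[[1]]$W[] <- v
      m
    }, tb$trunk[[1]]$dW
  )
  check_tensor(
    function(m) m$proj$W,
    function(m, v) {
      m$proj$W[] <- v
      m
    }, tb$proj$dW
  )
  check_tensor(
    function(m) m$head[[2]]$W,
    function(m, v) {
      m$head[[2]]$W[] <- v
      m
    }, hb$head[[2]]$dW
  )
})

test_that("monte-carlo prediction sets behave as the posterior sampler contract requires", {
  set.seed(44)
  img <- toy_image(32)
  m0 <- build_hbnet(tiny_cfg(drop_weight_rate = 0, seed = 6), handcrafted_dim = 0L)
  ms <- mc_predict(m0, img, T_mc = 5, seed = 1)
  expect_s3_class(ms, "mc_prediction_set")
  expect_equal(dim(ms$samples), c(5L, 8L))
  # rate 0: all passes identical, predictive mean equals the deterministic pass
  expect_true(all(apply(ms$samples, 2, function(x) diff(range(x)) == 0)))
  expect_equal(unname(colMeans(ms$samples)), unname(hbnet_forward(m0, img)))
  m3 <- build_hbnet(tiny_cfg(drop_weight_rate = 0.3, seed = 6), handcrafted_dim = 0L)
  s1 <- mc_predict(m3, img, T_mc = 50, seed = 9)
  expect_true(all(apply(s1$samples, 2, sd) > 0))
  s2 <- mc_predict(m3, img, T_mc = 50, seed = 9)
  expect_identical(s1$samples, s2$samples) # seeded determinism, bitwise
})

test_that("training reduces the loss, is deterministic, and checkpoints on validation", {
  set.seed(45)
  # two-label toy task encoded in solid colour planes: linearly separable
  n <- 60
  imgs <- list()
  Y <- matrix(0L, n, 2)
  for (i in seq_len(n)) {
    y <- c(rbinom(1, 1, 0.5), rbinom(1, 1, 0.5))
    px <- array(0, c(32, 32, 3))
    px[, , 1] <- 40 + 180 * y[1] # red channel codes label 1
    px[, , 3] <- 40 + 180 * y[2] # blue channel codes label 2
    px <- px + array(rnorm(length(px), 0, 4), dim(px))
    imgs[[i]] <- pmax(pmin(px, 255), 0)
    Y[i, ] <- y
  }
  names(imgs) <- sprintf("t%02d", seq_len(n))
  rownames(Y) <- names(imgs)
  tr <- 1:40
  va <- 41:60
  # noise-free optimisation: the separable-data oracle needs convergence,
  # and the Drop-Weights noise floor on a 12-unit head is tested elsewhere
  cfg <- tiny_cfg(
    n_labels = 2L, epochs = 60L, batch_size = 8L,
    drop_weight_rate = 0, seed = 11
  )
  d_tr <- hbnet_data(imgs[tr], Y[tr, ])
  d_va <- hbnet_data(imgs[va], Y[va, ])
  fit1 <- hbnet_train(build_hbnet(cfg, 0L), d_tr, d_va)
  log1 <- tidy(fit1)
  expect_lt(log1$loss[nrow(log1)], log1$loss[1])
  # best-on-validation checkpoint bookkeeping
  expect_equal(fit1$best_val_accuracy, max(log1$val_accuracy))
  expect_equal(log1$val_accuracy[fit1$best_epoch], fit1$best_val_accuracy)
  # separable task: near-perfect exact match on validation
  pv <- hbnet_predict_probs(fit1, imgs[va])
  expect_gte(exact_match(Y[va, ], (pv >= 0.5) * 1L), 0.9)
  # identical seed, identical run
  fit2 <- hbnet_train(build_hbnet(cfg, 0L), d_tr, d_va)
  expect_identical(tidy(fit2), log1)
  expect_identical(fit2$head[[1]]$W, fit1$head[[1]]$W)
  expect_error(
    hbnet_train(build_hbnet(cfg, 0L), d_tr, hbnet_data(imgs[tr][1], Y[tr[1], , drop = FALSE])),
    "overlap"
  )
  g <- glance(fit1)
  expect_equal(g$epochs_run, 60L)
})
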