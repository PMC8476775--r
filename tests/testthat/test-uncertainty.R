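test_that("predictive mean is the arithmetic mean and permutation invariant", {
  expect_equal(predictive_mean(c(0.2, 0.4, 0.6)), 0.4)
  expect_equal(predictive_mean(rep(0.37, 10)), 0.37)
  set.seed(1)
  s <- runif(50)
  expect_equal(predictive_mean(sample(s)), predictive_mean(s))
  expect_error(predictive_mean(numeric(0)), "at least one")
})

test_that("binary entropy matches the closed form in bits", {
  expect_equal(binary_entropy(0.5), 1)
  expect_equal(binary_entropy(0), 0)
  expect_equal(binary_entropy(1), 0)
  expect_equal(binary_entropy(0.9), 0.4690, tolerance = 1e-4)
  p <- seq(0.001, 0.999, length.out = 200)
  expect_equal(binary_entropy(p), -p * log2(p) - (1 - p) * log2(1 - p), tolerance = 1e-14)
  expect_error(binary_entropy(1.2), "\\[0, 1\\]")
})

test_that("jackknife entropy equals the brute-force leave-one-out oracle", {
  # constant samples: all leave-one-out means coincide, so the correction
  # vanishes and the plug-in value remains (0 at the degenerate endpoints)
  expect_equal(jackknife_entropy(rep(0.42, 10)), binary_entropy(0.42))
  expect_equal(jackknife_entropy(rep(1, 10)), 0)
  expect_equal(jackknife_entropy(rep(0, 10)), 0)
  set.seed(8)
  for (i in 1:50) {
    s <- runif(sample(2:64, 1))
    expect_equal(jackknife_entropy(s), brute_jackknife(s), tolerance = 1e-12)
  }
  expect_error(jackknife_entropy(0.5), "at least 2")
})

test_that("mutual information is the BALD decomposition, bounded by predictive entropy", {
  expect_equal(mutual_information(rep(0.3, 8)), 0)
  expect_equal(mutual_information(rep(c(0, 1), 10)), 1)
  set.seed(9)
  for (i in 1:20) {
    s <- runif(30)
    mi <- mutual_information(s)
    expect_gte(mi, 0)
    expect_lte(mi, binary_entropy(mean(s)) + 1e-12)
  }
})

test_that("CPPD is the gap between the two Bernoulli outcome probabilities", {
  expect_equal(cppd(rep(0.5, 4)), 0)
  expect_equal(cppd(rep(1, 4)), 1)
  expect_equal(cppd(rep(0, 4)), 1)
  expect_equal(cppd(c(0.7, 0.8)), 0.5) # mean 0.75 -> |2*0.75 - 1|
})

test_that("DHC score is CPPD over floored jackknife entropy, capped", {
  set.seed(10)
  s <- runif(40, 0.6, 0.9)
  sc <- dhc_score(s)
  expect_equal(sc$dhc_raw, sc$cppd / max(sc$h_jackknife, 1e-10))
  # certain constant prediction: zero entropy denominator hits the cap
  expect_equal(dhc_score(rep(1, 10))$dhc_raw, 1e6)
  # indifferent prediction: zero numerator
  expect_lt(dhc_score(c(0.45, 0.55, 0.5, 0.48, 0.52))$dhc_raw, 0.1)
})

test_that("DHC increases with separation and decreases with dispersion", {
  set.seed(12)
  # dispersion ladder at a fixed realised sample mean of 0.8 (the CPPD
  # numerator is then constant and only the entropy denominator moves)
  mean_dhc <- function(kappa, mu = 0.8, reps = 400, exact_mean = TRUE) {
    mean(replicate(reps, {
      x <- rbeta(50, mu * kappa, (1 - mu) * kappa)
      if (exact_mean) {
        x <- mu + (x - mean(x))
        while (any(x < 0 | x > 1)) x <- mu + 0.9 * (x - mu)
      }
      dhc_score(x)$dhc_raw
    }))
  }
  disp <- vapply(c(200, 50, 10, 4), mean_dhc, numeric(1))
  expect_true(all(diff(disp) < 0))
  # fixed concentration, mean moving away from 0.5
  sep <- vapply(
    c(0.55, 0.7, 0.85, 0.95),
    function(m) mean_dhc(50, mu = m, exact_mean = FALSE),
    numeric(1)
  )
  expect_true(all(diff(sep) > 0))
})

test_that("min-max normalisation maps batches into [0,1] and keeps ranks", {
  expect_equal(normalize_dhc(c(0, 5, 10)), c(0, 0.5, 1))
  expect_equal(normalize_dhc(rep(3.3, 5)), rep(1, 5))
  set.seed(13)
  x <- rexp(100)
  z <- normalize_dhc(x)
  expect_equal(order(z), order(x))
  expect_true(all(z >= 0 & z <= 1))
  expect_error(normalize_dhc(c(1, Inf)), "finite")
})

test_that("uncertainty records are permutation invariant in MC sample order", {
  set.seed(14)
  S <- matrix(runif(60 * 8), 60, 8)
  ms1 <- structure(list(image_id = "a", samples = S), class = "mc_prediction_set")
  ms2 <- structure(list(image_id = "a", samples = S[sample(60), ]), class = "mc_prediction_set")
  r1 <- uncertainty_records(list(ms1))
  r2 <- uncertainty_records(list(ms2))
  for (col in c("mu", "H_plugin", "H_jackknife", "mutual_info", "cppd", "dhc_raw")) {
    expect_equal(r1[[col]], r2[[col]], label = col)
  }
})

test_that("uncertainty records carry thresholds, truth, and per-label normalisation", {
  set.seed(15)
  mc <- purrr::map(1:4, function(i) {
    structure(
      list(image_id = paste0("im", i), samples = matrix(runif(30 * 8), 30, 8)),
      class = "mc_prediction_set"
    )
  })
  truth <- matrix(rbinom(32, 1, 0.5), 4, 8, dimnames = list(paste0("im", 1:4), cts))
  rec <- uncertainty_records(mc, truth = truth, prob_thresholds = 0.3)
  expect_equal(nrow(rec), 32)
  expect_identical(rec$call, as.integer(rec$mu >= 0.3))
  expect_false(anyNA(rec$manual_label))
  rng <- dplyr::summarise(
    dplyr::group_by(rec, cell_type),
    lo = min(dhc_normalized), hi = max(dhc_normalized)
  )
  expect_true(all(rng$lo >= 0 & rng$hi <= 1))
})
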