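test_that("hamming loss counts disagreeing cells", {
  Y <- matrix(c(1, 0, 0, 1), 2, 2, byrow = TRUE)
  expect_equal(hamming_loss(Y, Y), 0)
  expect_equal(hamming_loss(Y, 1 - Y), 1)
  P <- matrix(c(1, 1, 0, 1), 2, 2, byrow = TRUE)
  expect_equal(hamming_loss(Y, P), 0.25)
  expect_error(hamming_loss(Y, matrix(0, 3, 2)), "equal shape")
})

test_that("macro and micro F1 match their definitions", {
  Y <- cbind(c(1, 0), c(0, 1))
  expect_equal(f1_scores(Y, Y), list(macro_f1 = 1, micro_f1 = 1))
  # a label with no positives anywhere contributes 0 under the 0/0 := 0 rule
  Z <- cbind(c(1, 1), c(0, 0))
  expect_equal(f1_scores(Z, Z), list(macro_f1 = 0.5, micro_f1 = 1))
  # one label perfect, one all-wrong-with-positives
  Yt <- cbind(c(1, 0, 1), c(1, 1, 0))
  Yp <- cbind(c(1, 0, 1), c(0, 0, 1))
  expect_equal(f1_scores(Yt, Yp)$macro_f1, 0.5)
})

test_that("exact match is the fully-correct row fraction, bounded by per-label accuracy", {
  Yt <- matrix(c(1, 0, 0, 1, 1, 1), 3, 2, byrow = TRUE)
  Yp <- matrix(c(1, 0, 0, 1, 1, 0), 3, 2, byrow = TRUE)
  expect_equal(exact_match(Yt, Yp), 2 / 3, tolerance = 1e-9)
  set.seed(21)
  for (i in 1:20) {
    A <- matrix(rbinom(24, 1, 0.5), 6)
    B <- matrix(rbinom(24, 1, 0.5), 6)
    em <- exact_match(A, B)
    per_label_acc <- colMeans(A == B)
    expect_true(all(em <= per_label_acc + 1e-12))
  }
})

test_that("average precision follows the precision-at-positive-ranks tally", {
  expect_equal(
    mean_average_precision(matrix(c(1, 0, 1)), matrix(c(0.9, 0.8, 0.7))),
    (1 + 2 / 3) / 2
  )
  # perfect ranking
  expect_equal(
    mean_average_precision(matrix(c(1, 1, 0, 0)), matrix(c(0.9, 0.8, 0.2, 0.1))),
    1
  )
  expect_warning(
    m <- mean_average_precision(cbind(c(1, 0), c(0, 0)), cbind(c(0.9, 0.1), c(0.5, 0.6))),
    "skipped"
  )
  expect_equal(m, 1)
  expect_error(
    mean_average_precision(matrix(c(0, 0)), matrix(c(0.1, 0.2))),
    "no label"
  )
})

test_that("random-score average precision concentrates near prevalence", {
  set.seed(22)
  aps <- replicate(60, {
    y <- matrix(rbinom(200, 1, 0.3))
    s <- matrix(runif(200))
    mean_average_precision(y, s)
  })
  expect_gt(mean(aps), 0.2)
  expect_lt(mean(aps), 0.45)
})

test_that("MCC matches its closed form and zero-denominator convention", {
  expect_equal(mcc(2, 1, 0, 2), 4 / 6, tolerance = 1e-9)
  expect_equal(mcc(5, 0, 0, 5), 1)
  expect_equal(mcc(0, 5, 5, 0), -1)
  expect_equal(mcc(3, 0, 0, 0), 0) # degenerate: no negatives
})

test_that("all multilabel metrics agree with brute-force tallies on random instances", {
  set.seed(23)
  for (i in 1:300) {
    n <- sample(2:8, 1)
    C <- sample(2:4, 1)
    Yt <- matrix(rbinom(n * C, 1, 0.5), n)
    Yp <- matrix(rbinom(n * C, 1, 0.5), n)
    b <- brute_metrics(Yt, Yp)
    expect_equal(hamming_loss(Yt, Yp), b$hamming)
    expect_equal(exact_match(Yt, Yp), b$exact)
    f1 <- f1_scores(Yt, Yp)
    expect_equal(f1$macro_f1, b$macro_f1)
    expect_equal(f1$micro_f1, b$micro_f1)
  }
})

test_that("metrics are invariant to simultaneous row permutation", {
  set.seed(24)
  Yt <- matrix(rbinom(40, 1, 0.4), 10)
  Yp <- matrix(rbinom(40, 1, 0.4), 10)
  p <- sample(10)
  expect_equal(hamming_loss(Yt, Yp), hamming_loss(Yt[p, ], Yp[p, ]))
  expect_equal(exact_match(Yt, Yp), exact_match(Yt[p, ], Yp[p, ]))
  expect_equal(f1_scores(Yt, Yp), f1_scores(Yt[p, ], Yp[p, ]))
})

test_that("threshold grid search maximises per-label MCC with lowest-threshold ties", {
  # perfectly separated scores: chosen threshold in the separating gap
  set.seed(31)
  y <- c(rep(0, 10), rep(1, 10))
  s <- c(runif(10, 0.05, 0.30), runif(10, 0.62, 0.95))
  ts <- grid_search_thresholds(cbind(y), cbind(s))
  expect_gt(ts$prob_threshold, max(s[y == 0]))
  expect_lte(ts$prob_threshold, min(s[y == 1]))
  expect_equal(ts$mcc, 1)
  # ties resolve to the lowest grid threshold
  y2 <- c(0, 1)
  s2 <- c(0.1, 0.9)
  ts2 <- grid_search_thresholds(cbind(y2), cbind(s2))
  expect_equal(ts2$prob_threshold, 0.11)
  expect_error(grid_search_thresholds(cbind(y), cbind(s), grid = numeric(0)), "non-empty")
})

test_that("two-Gaussian score mixtures recover the Bayes midpoint threshold", {
  set.seed(25)
  n <- 2000
  y <- rbinom(n, 1, 0.5)
  s <- pmin(pmax(rnorm(n, ifelse(y == 1, 0.7, 0.3), 0.1), 0.001), 0.999)
  ts <- grid_search_thresholds(cbind(y), cbind(s))
  expect_lt(abs(ts$prob_threshold - 0.5), 0.05)
})

test_that("Kendall label correlation is tie-corrected tau-b with unit diagonal", {
  M <- cbind(a = c(0, 1, 2, 3, 1), b = c(0, 1, 2, 3, 1), c = c(3, 2, 1, 0, 2))
  expect_warning(K <- kendall_label_correlation(cbind(M, d = rep(2, 5))), "constant")
  expect_equal(unname(K["a", "b"]), 1)
  expect_equal(unname(K["a", "c"]), -1)
  expect_true(all(diag(K) == 1))
  expect_equal(unname(K[, "d"]), c(0, 0, 0, 1))
  # 5-row hand example against the O(n^2) pair-count oracle
  set.seed(26)
  x <- sample(0:3, 5, replace = TRUE)
  y <- sample(0:3, 5, replace = TRUE)
  K2 <- kendall_label_correlation(cbind(x, y))
  expect_equal(unname(K2[1, 2]), brute_taub(x, y), tolerance = 1e-12)
})

test_that("evaluation report assembles the full metric suite with confusion counts", {
  set.seed(27)
  Yt <- matrix(rbinom(80, 1, 0.4), 10, dimnames = list(NULL, cts))
  Yp <- matrix(rbinom(80, 1, 0.4), 10, dimnames = list(NULL, cts))
  ev <- evaluate_multilabel(Yt, Yp, scores = matrix(runif(80), 10))
  expect_s3_class(ev, "ihc_evaluation")
  expect_equal(ev$per_label$tp + ev$per_label$fp + ev$per_label$fn + ev$per_label$tn, rep(10, 8))
  expect_true(all(ev$per_label$mcc >= -1 & ev$per_label$mcc <= 1))
  expect_equal(glance(ev)$hamming_loss, hamming_loss(Yt, Yp))
  expect_equal(nrow(tidy(ev)), 8)
})

test_that("accuracy can be grouped by annotation facets", {
  ann <- validate_annotations(toy_annotations(6, seed = 30))
  Y <- annotation_labels(ann)
  rec <- purrr::map_dfr(cts, function(ct) {
    tibble::tibble(
      image_id = ann$image_id, cell_type = ct,
      call = Y[, ct], manual_label = Y[, ct]
    )
  })
  byint <- accuracy_by_annotation(rec, ann, "intensity")
  expect_true(all(byint$accuracy == 1))
  expect_equal(sum(byint$n), 48)
})
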