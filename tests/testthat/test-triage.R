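test_that("ranking by DHC is ascending with lexicographic tie-breaks and idempotent", {
  rec <- records_from_scores(
    dhc = c(0.9, 0.1, 0.5),
    call = c(1, 1, 1), truth = c(1, 1, 1)
  )
  expect_equal(rank_by_dhc(rec, "leydig"), c("im_0002", "im_0003", "im_0001"))
  tie <- records_from_scores(dhc = rep(0.4, 3), call = rep(1, 3), truth = rep(1, 3))
  expect_equal(rank_by_dhc(tie, "leydig"), sort(tie$image_id))
  ord <- rank_by_dhc(rec, "leydig")
  rec_sorted <- rec[match(ord, rec$image_id), ]
  expect_equal(rank_by_dhc(rec_sorted, "leydig"), ord)
})

test_that("cutoff selection finds the misclassification boundary on a constructed fixture", {
  set.seed(51)
  n <- 400
  # misclassifications concentrated below dhc 0.2; correct records uniform
  dhc <- c(runif(n * 0.9, 0, 1), runif(n * 0.1, 0, 0.2))
  correct <- c(rep(TRUE, n * 0.9), rep(FALSE, n * 0.1))
  truth <- rbinom(n, 1, 0.5)
  call <- ifelse(correct, truth, 1 - truth)
  rec <- records_from_scores(dhc, call, truth)
  cut <- select_cutoff(rec, "leydig", target_accuracy = 0.99, min_retained_fraction = 0.5)
  expect_gt(cut, 0.15)
  expect_lt(cut, 0.25)
  tri <- apply_cutoffs(rec, c(leydig = cut))
  expect_gte(tri$summary$retained_accuracy, 0.99)
  # all-correct validation: nothing needs discarding
  rec_ok <- records_from_scores(runif(50), call = truth[1:50], truth = truth[1:50])
  expect_equal(select_cutoff(rec_ok, "leydig"), 0)
  # unattainable target under a full-retention constraint warns and returns 0
  rec_bad <- records_from_scores(runif(50), call = 1 - truth[1:50], truth = truth[1:50])
  expect_warning(
    c0 <- select_cutoff(rec_bad, "leydig", target_accuracy = 0.99, min_retained_fraction = 1),
    "unattainable"
  )
  expect_equal(c0, 0)
})

test_that("applying cutoffs conserves records and reports the discard trade-off", {
  set.seed(52)
  n <- 100
  truth <- rbinom(n, 1, 0.5)
  rec <- records_from_scores(runif(n), call = truth, truth = truth)
  tri0 <- apply_cutoffs(rec, c(leydig = 0))
  expect_equal(tri0$summary$discard_fraction, 0)
  expect_equal(tri0$summary$n_retained, n)
  tri1 <- apply_cutoffs(rec, c(leydig = 2)) # above every score
  expect_equal(tri1$summary$discard_fraction, 1)
  expect_true(is.na(tri1$summary$retained_accuracy))
  a <- tri0$assignments$leydig
  expect_setequal(c(a$retained, a$discarded), rec$image_id)
  expect_length(intersect(a$retained, a$discarded), 0)
  g <- glance(tri0)
  expect_equal(g$n_labels, 1L)
})

test_that("accuracy-discard curve is well-behaved at its endpoints", {
  set.seed(53)
  truth <- rbinom(80, 1, 0.5)
  rec <- records_from_scores(runif(80), call = truth, truth = truth)
  curve <- accuracy_discard_curve(rec, "leydig")
  expect_true(all(curve$retained_accuracy == 1))
  expect_equal(curve$discard_fraction[1], 0) # lowest observed score retains all
  expect_true(all(diff(curve$discard_fraction) >= 0))
  expect_true(all(diff(curve$n_retained) <= 0))
})

test_that("confidence map data ranks every record exactly once", {
  set.seed(54)
  truth <- rbinom(30, 1, 0.4)
  call <- ifelse(runif(30) < 0.8, truth, 1 - truth)
  rec <- records_from_scores(runif(30), call, truth)
  cm <- confidence_map_data(rec)
  expect_equal(sort(cm$rank), 1:30)
  expect_equal(cm$correct, (cm$image_id |>
    match(rec$image_id) |>
    (\(i) rec$call[i] == rec$manual_label[i])()))
  expect_true(all(diff(cm$dhc_normalized) >= 0))
})

test_that("the reference cutoff preset carries the per-cell-type values", {
  ps <- dhc_cutoff_preset("hpa_testis_v1")
  expect_equal(unname(ps["round_early_spermatids"]), 0.78)
  expect_equal(unname(ps["sertoli"]), 1e-10)
  expect_equal(unname(ps["spermatogonia"]), 0.11)
  expect_length(ps, 8)
})

test_that("triage and confidence plots build without error", {
  set.seed(55)
  truth <- rbinom(60, 1, 0.5)
  call <- ifelse(runif(60) < 0.85, truth, 1 - truth)
  rec <- records_from_scores(runif(60), call, truth)
  expect_s3_class(plot_confidence_map(rec, cutoffs = c(leydig = 0.2)), "ggplot")
  expect_s3_class(plot_accuracy_discard(rec), "ggplot")
  expect_s3_class(autoplot(apply_cutoffs(rec, c(leydig = 0.2))), "ggplot")
})
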