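# Shared fixtures: tiny images, annotation tables and brute-force oracles
# used across test files. Everything is generated in code at test time.

cts <- cell_type_vocabulary()

`%||%` <- function(a, b) if (is.null(a)) b else a

# deterministic small RGB test image (side x side x 3, 0..255)
toy_image <- function(side = 64, seed = 1) {
  set.seed(seed)
  array(sample(0:255, side * side * 3, replace = TRUE), c(side, side, 3))
}

# minimal well-formed annotation tibble for n images
toy_annotations <- function(n = 3, seed = 1) {
  set.seed(seed)
  ann <- tibble::tibble(
    image_id = sprintf("img_%02d", seq_len(n)),
    split = rep("train", n)
  )
  for (ct in cts) {
    iv <- sample(0:3, n, replace = TRUE)
    lv <- ifelse(iv > 0, sample(c("cytoplasm", "nucleus", "cytoplasm+membrane"),
      n,
      replace = TRUE
    ), "")
    ann[[paste0(ct, "_intensity")]] <- iv
    ann[[paste0(ct, "_location")]] <- lv
  }
  ann
}

# brute-force leave-one-out jackknife entropy (independent of the closed
# form used in the package)
brute_jackknife <- function(s) {
  T_mc <- length(s)
  h <- function(p) {
    f <- function(q) ifelse(q > 0, -q * log2(q), 0)
    f(p) + f(1 - p)
  }
  loo <- vapply(seq_len(T_mc), function(i) h(mean(s[-i])), numeric(1))
  T_mc * h(mean(s)) - (T_mc - 1) * mean(loo)
}

# brute-force per-cell multilabel metric tallies
brute_metrics <- function(Yt, Yp) {
  n <- nrow(Yt)
  C <- ncol(Yt)
  dis <- 0
  em <- 0
  f1s <- numeric(C)
  tp_all <- fp_all <- fn_all <- 0
  for (i in seq_len(n)) {
    row_ok <- TRUE
    for (c in seq_len(C)) {
      if (Yt[i, c] != Yp[i, c]) {
        dis <- dis + 1
        row_ok <- FALSE
      }
    }
    if (row_ok) em <- em + 1
  }
  for (c in seq_len(C)) {
    tp <- fp <- fn <- 0
    for (i in seq_len(n)) {
      if (Yt[i, c] == 1 && Yp[i, c] == 1) tp <- tp + 1
      if (Yt[i, c] == 0 && Yp[i, c] == 1) fp <- fp + 1
      if (Yt[i, c] == 1 && Yp[i, c] == 0) fn <- fn + 1
    }
    f1s[c] <- if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
    tp_all <- tp_all + tp
    fp_all <- fp_all + fp
    fn_all <- fn_all + fn
  }
  micro <- if (2 * tp_all + fp_all + fn_all == 0) 0 else 2 * tp_all / (2 * tp_all + fp_all + fn_all)
  list(
    hamming = dis / (n * C), exact = em / n,
    macro_f1 = mean(f1s), micro_f1 = micro
  )
}

# O(n^2) pair-count Kendall tau-b
brute_taub <- function(x, y) {
  n <- length(x)
  C <- D <- tx <- ty <- 0
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      a <- sign(x[j] - x[i])
      b <- sign(y[j] - y[i])
      if (a == 0 && b == 0) next
      if (a == 0) tx <- tx + 1 else if (b == 0) ty <- ty + 1 else if (a == b) C <- C + 1 else D <- D + 1
    }
  }
  (C - D) / sqrt((C + D + tx) * (C + D + ty))
}

# uncertainty records built straight from per-(image,label) scores: handy
# for triage tests that do not need a model
records_from_scores <- function(dhc, call, truth, label = "leydig") {
  n <- length(dhc)
  tibble::tibble(
    image_id = sprintf("im_%04d", seq_len(n)),
    cell_type = label,
    mu = pmin(pmax(call, 0.01), 0.99),
    H_plugin = 0.5, H_jackknife = 0.5, mutual_info = 0, cppd = 0.5,
    dhc_raw = dhc, dhc_normalized = dhc,
    call = as.integer(call), manual_label = as.integer(truth)
  )
}
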