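#' Predictive mean of Monte-Carlo samples
#'
#' Arithmetic mean of the per-pass probabilities; the model's point
#' prediction for one label.
#'
#' @param samples Numeric vector of probabilities (one per stochastic pass).
#' @return Scalar in `[0, 1]`.
#' @export
predictive_mean <- function(samples) {
  if (length(samples) < 1L) stop("need at least one sample", call. = FALSE)
  mean(samples)
}

#' Binary Shannon entropy in bits
#'
#' `H(p) = -p log2 p - (1-p) log2(1-p)` with `0 log 0 := 0`; non-negative,
#' maximal (1 bit) at `p = 0.5`. Using bits keeps the per-label entropy on a
#' normalised 0..1 scale.
#'
#' @param p Probability (vectorised), in `[0, 1]`.
#' @return Entropy in bits.
#' @export
binary_entropy <- function(p) {
  if (any(p < 0 | p > 1, na.rm = FALSE)) stop("p must lie in [0, 1]", call. = FALSE)
  term <- function(q) ifelse(q > 0, -q * log2(q), 0)
  term(p) + term(1 - p)
}

#' Jackknife bias-corrected entropy
#'
#' The plug-in entropy `H(mean(samples))` is downward-biased at finite T.
#' The jackknife correction `T * H(mu) - (T-1) * mean_i H(mu_(-i))`, with
#' `mu_(-i)` the leave-one-out means, removes the leading 1/T bias term. The
#' corrected value can overshoot slightly negative near degenerate means.
#'
#' @param samples Numeric vector of probabilities, length >= 2.
#' @return Bias-corrected entropy in bits.
#' @export
jackknife_entropy <- function(samples) {
  T_mc <- length(samples)
  if (T_mc < 2L) stop("jackknife entropy needs at least 2 samples", call. = FALSE)
  mu <- mean(samples)
  loo <- (T_mc * mu - samples) / (T_mc - 1)
  loo <- pmin(pmax(loo, 0), 1) # guard rounding at the boundary
  T_mc * binary_entropy(mu) - (T_mc - 1) * mean(binary_entropy(loo))
}

#' Mutual information between prediction and posterior draws
#'
#' Approximated as the entropy of the predictive distribution minus the mean
#' entropy across stochastic passes (the BALD decomposition); clamped at 0.
#'
#' @inheritParams jackknife_entropy
#' @return Mutual information in bits.
#' @export
mutual_information <- function(samples) {
  if (length(samples) < 2L) stop("mutual information needs at least 2 samples", call. = FALSE)
  mi <- binary_entropy(mean(samples)) - mean(binary_entropy(samples))
  max(mi, 0)
}

#' Class predictive probability distance (CPPD)
#'
#' The gap between the highest and second-highest outcome probabilities.
#' Under the per-label Bernoulli convention the two outcomes of one sigmoid
#' label have probabilities `mu` and `1 - mu`, so `CPPD = |2 mu - 1|`.
#'
#' @inheritParams predictive_mean
#' @return Scalar in `[0, 1]`.
#' @export
cppd <- function(samples) {
  abs(2 * predictive_mean(samples) - 1)
}

#' DHC confidence score for one label
#'
#' `DHC = CPPD / H_J`, the class predictive probability distance divided by
#' the jackknife bias-corrected entropy. A ratio near 1 means distance and
#' uncertainty are comparable; a ratio tending to infinity means uncertainty
#' is much smaller than the class-membership difference (high confidence); a
#' ratio near 0 marks an uncertain prediction. The denominator is floored at
#' `epsilon` (the jackknife estimate can reach 0 or slightly below) and the
#' ratio capped at `cap` so tables stay finite; the cap sorts as the top
#' rank.
#'
#' @inheritParams jackknife_entropy
#' @param epsilon Denominator floor.
#' @param cap Upper bound for the reported raw ratio.
#' @return A list with `dhc_raw`, `cppd`, `h_jackknife`.
#' @export
dhc_score <- function(samples, epsilon = 1e-10, cap = 1e6) {
  hj <- jackknife_entropy(samples)
  cp <- cppd(samples)
  list(dhc_raw = min(cp / max(hj, epsilon), cap), cppd = cp, h_jackknife = hj)
}

#' Min-max normalise raw DHC scores over a scored batch
#'
#' Rescales `(x - min) / (max - min)` to `[0, 1]` within the batch being
#' reported (done per label). A batch of identical scores maps to 1
#' (fully concordant). Rank order is preserved.
#'
#' @param raw Numeric vector of raw DHC scores (finite; the cap counts as
#'   finite).
#' @return Numeric vector in `[0, 1]`.
#' @export
normalize_dhc <- function(raw) {
  if (length(raw) < 1L || !all(is.finite(raw))) {
    stop("need at least one finite score", call. = FALSE)
  }
  rng <- range(raw)
  if (rng[1] == rng[2]) return(rep(1, length(raw)))
  (raw - rng[1]) / (rng[2] - rng[1])
}

#' Per-label uncertainty records for a batch of MC prediction sets
#'
#' Turns Monte-Carlo prediction sets into the long uncertainty table: one row
#' per (image, cell type) with predictive mean, plug-in and jackknife
#' entropies, mutual information, CPPD, raw and batch-normalised DHC score,
#' the thresholded call, and the manual label when known.
#'
#' @param mc_sets List of `"mc_prediction_set"` objects.
#' @param cell_types Label names (length C).
#' @param truth Optional `n x C` binary matrix of manual labels (rownames =
#'   image ids).
#' @param prob_thresholds Per-label probability thresholds for the binary
#'   call (recycled scalar allowed; default 0.5).
#' @param cppd_mode `"per_label"` or `"across_labels"` (see [ihc_config()]).
#' @param epsilon,cap Passed to [dhc_score()].
#' @return A tibble with class `"ihc_uncertainty"`.
#' @export
uncertainty_records <- function(mc_sets, cell_types = cell_type_vocabulary(),
                                truth = NULL, prob_thresholds = 0.5,
                                cppd_mode = c("per_label", "across_labels"),
                                epsilon = 1e-10, cap = 1e6) {
  cppd_mode <- match.arg(cppd_mode)
  C <- length(cell_types)
  thr <- rep_len(prob_thresholds, C)
  rows <- purrr::map(mc_sets, function(ms) {
    S <- ms$samples
    if (nrow(S) < 2L) stop("uncertainty needs T >= 2 MC samples", call. = FALSE)
    mus <- colMeans(S)
    per_label <- purrr::map(seq_len(C), function(c) {
      s <- S[, c]
      sc <- dhc_score(s, epsilon = epsilon, cap = cap)
      cp <- if (cppd_mode == "per_label") {
        sc$cppd
      } else {
        srt <- sort(mus, decreasing = TRUE)
        srt[1] - srt[2]
      }
      tibble::tibble(
        image_id = ms$image_id,
        cell_type = cell_types[c],
        mu = mus[c],
        H_plugin = binary_entropy(mus[c]),
        H_jackknife = sc$h_jackknife,
        mutual_info = mutual_information(s),
        cppd = cp,
        dhc_raw = min(cp / max(sc$h_jackknife, epsilon), cap),
        call = as.integer(mus[c] >= thr[c])
      )
    })
    dplyr::bind_rows(per_label)
  })
  tbl <- dplyr::bind_rows(rows)
  tbl <- tbl |>
    dplyr::group_by(.data$cell_type) |>
    dplyr::mutate(dhc_normalized = normalize_dhc(.data$dhc_raw)) |>
    dplyr::ungroup()
  if (!is.null(truth)) {
    truth_long <- tibble::tibble(
      image_id = rep(rownames(truth), times = ncol(truth)),
      cell_type = rep(colnames(truth), each = nrow(truth)),
      manual_label = as.integer(as.vector(truth))
    )
    tbl <- dplyr::left_join(tbl, truth_long, by = c("image_id", "cell_type"))
  } else {
    tbl$manual_label <- NA_integer_
  }
  tbl <- dplyr::relocate(
    tbl, "image_id", "cell_type", "mu", "H_plugin", "H_jackknife",
    "mutual_info", "cppd", "dhc_raw", "dhc_normalized", "call", "manual_label"
  )
  class(tbl) <- unique(c("ihc_uncertainty", class(tbl)))
  tbl
}
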