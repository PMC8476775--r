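check_shapes <- function(Y_true, Y_pred) {
  if (!all(dim(Y_true) == dim(Y_pred))) {
    stop("truth and prediction matrices must have equal shape", call. = FALSE)
  }
}

#' Hamming loss
#'
#' Fraction of individual (image, label) cells on which prediction and truth
#' disagree; 0 is perfect.
#'
#' @param Y_true,Y_pred `n x C` binary matrices.
#' @return Scalar in `[0, 1]`.
#' @export
hamming_loss <- function(Y_true, Y_pred) {
  check_shapes(Y_true, Y_pred)
  mean(Y_true != Y_pred)
}

#' Macro and micro F1 scores
#'
#' Macro F1 averages the per-label F1 (0/0 defined as 0) without weighting;
#' micro F1 pools true/false positives and negatives over all labels first.
#'
#' @inheritParams hamming_loss
#' @return Named list with `macro_f1` and `micro_f1`.
#' @export
f1_scores <- function(Y_true, Y_pred) {
  check_shapes(Y_true, Y_pred)
  tp <- colSums(Y_true == 1 & Y_pred == 1)
  fp <- colSums(Y_true == 0 & Y_pred == 1)
  fn <- colSums(Y_true == 1 & Y_pred == 0)
  f1 <- ifelse(2 * tp + fp + fn > 0, 2 * tp / (2 * tp + fp + fn), 0)
  micro <- if (sum(2 * tp + fp + fn) > 0) 2 * sum(tp) / sum(2 * tp + fp + fn) else 0
  list(macro_f1 = mean(f1), micro_f1 = micro)
}

#' Exact match ratio
#'
#' Fraction of images whose full label vector is predicted correctly — the
#' strictest multilabel metric.
#'
#' @inheritParams hamming_loss
#' @return Scalar in `[0, 1]`.
#' @export
exact_match <- function(Y_true, Y_pred) {
  check_shapes(Y_true, Y_pred)
  mean(rowSums(Y_true != Y_pred) == 0)
}

average_precision <- function(y, s) {
  ord <- order(s, decreasing = TRUE) # ties: stable original order
  y <- y[ord]
  hits <- cumsum(y)
  prec <- hits / seq_along(y)
  sum(prec[y == 1]) / sum(y)
}

#' Mean average precision over labels
#'
#' All-point average precision of the score-descending ranking, computed per
#' label and averaged without weighting. Labels without any positive example
#' are skipped with a warning; if no label has positives this is an error.
#'
#' @param Y_true `n x C` binary matrix.
#' @param scores `n x C` numeric score matrix.
#' @return Scalar in `[0, 1]`.
#' @export
mean_average_precision <- function(Y_true, scores) {
  check_shapes(Y_true, scores)
  pos <- colSums(Y_true) > 0
  if (!any(pos)) stop("no label has a positive example", call. = FALSE)
  if (!all(pos)) {
    warning(sum(!pos), " label(s) without positives skipped in mAP", call. = FALSE)
  }
  aps <- vapply(
    which(pos),
    function(c) average_precision(Y_true[, c], scores[, c]),
    numeric(1)
  )
  mean(aps)
}

#' Matthews correlation coefficient
#'
#' MCC from confusion counts; any zero factor in the denominator yields 0.
#'
#' @param tp,fp,fn,tn Confusion counts.
#' @return Scalar in `[-1, 1]`.
#' @export
mcc <- function(tp, fp, fn, tn) {
  tp <- as.numeric(tp)
  fp <- as.numeric(fp)
  fn <- as.numeric(fn)
  tn <- as.numeric(tn)
  den2 <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (den2 == 0) return(0)
  (tp * tn - fp * fn) / sqrt(den2)
}

#' MCC-optimal per-label probability thresholds
#'
#' For each label independently, picks the grid threshold maximising the MCC
#' of the binarised scores against the truth (ties broken toward the lowest
#' threshold).
#'
#' @param Y_true `n x C` binary matrix.
#' @param scores `n x C` matrix of predicted probabilities.
#' @param grid Candidate thresholds in `(0, 1)`; default 0.01..0.99 step
#'   0.01.
#' @param dhc_cutoffs Optional per-label DHC cutoffs stored alongside.
#' @return A tibble with class `"ihc_thresholds"`: `cell_type`,
#'   `prob_threshold`, `mcc`, `dhc_cutoff`.
#' @export
grid_search_thresholds <- function(Y_true, scores, grid = seq(0.01, 0.99, by = 0.01),
                                   dhc_cutoffs = NA_real_) {
  check_shapes(Y_true, scores)
  if (length(grid) == 0L || any(grid <= 0 | grid >= 1)) {
    stop("grid must be a non-empty subset of (0, 1)", call. = FALSE)
  }
  C <- ncol(Y_true)
  labels <- colnames(Y_true) %||% paste0("label_", seq_len(C))
  cutoffs <- rep_len(dhc_cutoffs, C)
  rows <- purrr::map(seq_len(C), function(c) {
    y <- Y_true[, c]
    s <- scores[, c]
    mccs <- vapply(grid, function(t) {
      p <- as.integer(s >= t)
      mcc(sum(y == 1 & p == 1), sum(y == 0 & p == 1), sum(y == 1 & p == 0), sum(y == 0 & p == 0))
    }, numeric(1))
    best <- which.max(mccs) # which.max returns the first (lowest) maximiser
    tibble::tibble(
      cell_type = labels[c], prob_threshold = grid[best],
      mcc = mccs[best], dhc_cutoff = cutoffs[c]
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- unique(c("ihc_thresholds", class(out)))
  out
}

#' Reference per-label DHC cutoffs for the testis workflow
#'
#' The named preset `hpa_testis_v1` ships the per-cell-type normalised DHC
#' cutoffs determined on the original testis collection: 0.11 for
#' spermatogonia, preleptotene spermatocytes and Leydig cells, 0.22 for
#' pachytene spermatocytes and elongated/late spermatids, 0.78 for
#' round/early spermatids, and 1e-10 for Sertoli and peritubular cells.
#'
#' @param preset Preset name (currently only `"hpa_testis_v1"`).
#' @return Named numeric vector of cutoffs in cell-type vocabulary order.
#' @export
dhc_cutoff_preset <- function(preset = "hpa_testis_v1") {
  preset <- match.arg(preset)
  stats::setNames(
    c(0.11, 0.11, 0.22, 0.78, 0.22, 1e-10, 0.11, 1e-10),
    cell_type_vocabulary()
  )
}

#' Multilabel evaluation report
#'
#' Computes the full metric suite (Hamming loss, macro/micro F1, exact match
#' ratio, mean average precision) together with per-label confusion counts,
#' accuracies and MCC.
#'
#' @param Y_true,Y_pred `n x C` binary matrices.
#' @param scores Optional `n x C` probability matrix for mAP (defaults to
#'   `Y_pred`).
#' @return A list with class `"ihc_evaluation"`: scalar metrics plus a
#'   `per_label` tibble.
#' @export
evaluate_multilabel <- function(Y_true, Y_pred, scores = NULL) {
  check_shapes(Y_true, Y_pred)
  labels <- colnames(Y_true) %||% paste0("label_", seq_len(ncol(Y_true)))
  f1 <- f1_scores(Y_true, Y_pred)
  per_label <- purrr::map(seq_len(ncol(Y_true)), function(c) {
    y <- Y_true[, c]
    p <- Y_pred[, c]
    tp <- sum(y == 1 & p == 1)
    fp <- sum(y == 0 & p == 1)
    fn <- sum(y == 1 & p == 0)
    tn <- sum(y == 0 & p == 0)
    tibble::tibble(
      cell_type = labels[c], tp = tp, fp = fp, fn = fn, tn = tn,
      accuracy = (tp + tn) / length(y), mcc = mcc(tp, fp, fn, tn)
    )
  })
  structure(
    list(
      n = nrow(Y_true),
      hamming_loss = hamming_loss(Y_true, Y_pred),
      macro_f1 = f1$macro_f1,
      micro_f1 = f1$micro_f1,
      exact_match = exact_match(Y_true, Y_pred),
      mean_average_precision = mean_average_precision(Y_true, scores %||% Y_pred),
      per_label = dplyr::bind_rows(per_label)
    ),
    class = "ihc_evaluation"
  )
}

#' @export
print.ihc_evaluation <- function(x, ...) {
  cat("Multilabel evaluation report (n =", x$n, "images)\n")
  cat(sprintf("  Hamming loss       %.4f\n", x$hamming_loss))
  cat(sprintf("  Macro F1           %.4f\n", x$macro_f1))
  cat(sprintf("  Micro F1           %.4f\n", x$micro_f1))
  cat(sprintf("  Exact match ratio  %.4f\n", x$exact_match))
  cat(sprintf("  Mean avg precision %.4f\n", x$mean_average_precision))
  cat("Per-label confusion:\n")
  print(x$per_label)
  invisible(x)
}

#' Pairwise Kendall correlation of cell-type intensities
#'
#' Tie-corrected Kendall tau-b between the per-image intensity columns of
#' each cell-type pair — the summary behind the cell-type co-expression
#' cluster heatmap. Constant columns correlate as 0 (with a warning);
#' diagonal is 1.
#'
#' @param intensities `n x C` integer matrix (0..3).
#' @return `C x C` symmetric correlation matrix.
#' @export
kendall_label_correlation <- function(intensities) {
  M <- as.matrix(intensities)
  if (nrow(M) < 2L) stop("need at least 2 images", call. = FALSE)
  constant <- apply(M, 2, function(x) length(unique(x)) == 1L)
  if (any(constant)) {
    warning("constant column(s) ", paste(which(constant), collapse = ", "),
      ": correlation defined as 0",
      call. = FALSE
    )
  }
  K <- suppressWarnings(stats::cor(M, method = "kendall"))
  K[!is.finite(K)] <- 0
  diag(K) <- 1
  K
}

#' Accuracy report grouped by an annotation facet
#'
#' Generic group-by behind the per-subcellular-location and per-intensity
#' accuracy breakdowns: joins uncertainty records (with calls and manual
#' labels) to the annotation table and tabulates per-label accuracy within
#' each group.
#'
#' @param records An `"ihc_uncertainty"` tibble with `manual_label` known.
#' @param annotations The matching annotation tibble.
#' @param facet `"intensity"` or `"location"`.
#' @return Tibble: `cell_type`, facet value, `n`, `accuracy`.
#' @export
accuracy_by_annotation <- function(records, annotations, facet = c("intensity", "location")) {
  facet <- match.arg(facet)
  cell_types <- attr(annotations, "cell_types") %||% cell_type_vocabulary()
  long <- purrr::map(cell_types, function(ct) {
    tibble::tibble(
      image_id = annotations$image_id,
      cell_type = ct,
      facet_value = as.character(annotations[[paste0(ct, "_", facet)]])
    )
  })
  long <- dplyr::bind_rows(long)
  records |>
    dplyr::inner_join(long, by = c("image_id", "cell_type")) |>
    dplyr::group_by(.data$cell_type, .data$facet_value) |>
    dplyr::summarise(
      n = dplyr::n(),
      accuracy = mean(.data$call == .data$manual_label),
      .groups = "drop"
    )
}
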