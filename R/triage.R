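label_records <- function(records, label) {
  out <- dplyr::filter(records, .data$cell_type == label)
  if (nrow(out) == 0L) stop("no records for label '", label, "'", call. = FALSE)
  out
}

#' Rank image ids by ascending DHC score
#'
#' Ascending order of the normalised DHC score for one label, i.e. most
#' uncertain first; ties break by image id for determinism.
#'
#' @param records An `"ihc_uncertainty"` tibble.
#' @param label Cell-type name.
#' @param score Column used for ranking (default `dhc_normalized`).
#' @return Character vector of image ids.
#' @export
rank_by_dhc <- function(records, label, score = "dhc_normalized") {
  r <- label_records(records, label)
  r$image_id[order(r[[score]], r$image_id)]
}

#' Select a per-label DHC cutoff from validation data
#'
#' Returns the smallest cutoff c (searched over the observed normalised
#' scores and 0) such that the accuracy among validation records with
#' `dhc_normalized >= c` reaches `target_accuracy`, while retaining at least
#' `min_retained_fraction` of the records. When no admissible cutoff reaches
#' the target, the accuracy-maximising admissible cutoff is returned with a
#' warning. This formalises reading the spread of misclassifications off the
#' confidence map.
#'
#' @param records Validation `"ihc_uncertainty"` tibble with `manual_label`.
#' @param label Cell-type name.
#' @param target_accuracy Desired accuracy among retained records.
#' @param min_retained_fraction Minimum fraction of records kept.
#' @return Scalar cutoff.
#' @export
select_cutoff <- function(records, label, target_accuracy = 0.95,
                          min_retained_fraction = 0.5) {
  if (target_accuracy <= 0 || target_accuracy > 1) {
    stop("target_accuracy must lie in (0, 1]", call. = FALSE)
  }
  r <- label_records(records, label)
  if (anyNA(r$manual_label)) stop("validation records need manual labels", call. = FALSE)
  n <- nrow(r)
  cand <- sort(unique(c(0, r$dhc_normalized)))
  best <- list(cutoff = 0, acc = -Inf)
  for (c in cand) {
    keep <- r$dhc_normalized >= c
    if (sum(keep) < min_retained_fraction * n || sum(keep) == 0L) next
    acc <- mean(r$call[keep] == r$manual_label[keep])
    if (acc >= target_accuracy) return(c)
    if (acc > best$acc) best <- list(cutoff = c, acc = acc)
  }
  warning("label '", label, "': target accuracy ", target_accuracy,
    " unattainable at min_retained_fraction = ", min_retained_fraction,
    "; returning accuracy-maximising cutoff ", signif(best$cutoff, 3),
    call. = FALSE
  )
  best$cutoff
}

#' Select cutoffs for all labels
#'
#' @inheritParams select_cutoff
#' @param labels Cell types to process (default: all present).
#' @return Named numeric vector of cutoffs.
#' @export
select_cutoffs <- function(records, labels = NULL, target_accuracy = 0.95,
                           min_retained_fraction = 0.5) {
  labels <- labels %||% unique(records$cell_type)
  vapply(labels, function(l) {
    select_cutoff(records, l, target_accuracy, min_retained_fraction)
  }, numeric(1))
}

#' Split predictions into auto-accepted and manual-review sets
#'
#' Per label, records with `dhc_normalized >= cutoff` are retained
#' (auto-labelled); the rest are routed to manual review. When manual labels
#' are available the retained accuracy is reported (NA when everything is
#' discarded).
#'
#' @param records An `"ihc_uncertainty"` tibble.
#' @param cutoffs Named numeric vector of per-label cutoffs (names =
#'   cell types), or a single value recycled.
#' @return A list with class `"ihc_triage"`: a `summary` tibble (cell_type,
#'   cutoff, n, n_retained, discard_fraction, overall_accuracy,
#'   retained_accuracy) and `assignments` (per label, retained / discarded
#'   id lists).
#' @export
apply_cutoffs <- function(records, cutoffs) {
  labels <- unique(records$cell_type)
  if (is.null(names(cutoffs))) {
    cutoffs <- stats::setNames(rep_len(cutoffs, length(labels)), labels)
  }
  missing <- setdiff(labels, names(cutoffs))
  if (length(missing)) {
    stop("no cutoff for label(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  assignments <- list()
  rows <- purrr::map(labels, function(l) {
    r <- label_records(records, l)
    keep <- r$dhc_normalized >= cutoffs[[l]]
    assignments[[l]] <<- list(
      retained = sort(r$image_id[keep]),
      discarded = sort(r$image_id[!keep])
    )
    has_truth <- !anyNA(r$manual_label)
    tibble::tibble(
      cell_type = l,
      cutoff = cutoffs[[l]],
      n = nrow(r),
      n_retained = sum(keep),
      discard_fraction = mean(!keep),
      overall_accuracy = if (has_truth) mean(r$call == r$manual_label) else NA_real_,
      retained_accuracy = if (has_truth && any(keep)) {
        mean(r$call[keep] == r$manual_label[keep])
      } else {
        NA_real_
      }
    )
  })
  structure(
    list(summary = dplyr::bind_rows(rows), assignments = assignments),
    class = "ihc_triage"
  )
}

#' @export
print.ihc_triage <- function(x, ...) {
  cat("DHC triage summary\n")
  print(x$summary)
  invisible(x)
}

#' Accuracy vs discard trade-off curve
#'
#' Evaluates, at every distinct normalised DHC score for one label, the
#' accuracy among retained records and the fraction discarded — the direct
#' trade-off between accuracy and the number of images routed to manual
#' review.
#'
#' @inheritParams rank_by_dhc
#' @return Tibble: `cutoff`, `n_retained`, `retained_accuracy`,
#'   `discard_fraction` (discard fraction is non-decreasing in cutoff).
#' @export
accuracy_discard_curve <- function(records, label) {
  r <- label_records(records, label)
  if (anyNA(r$manual_label)) stop("curve needs manual labels", call. = FALSE)
  cand <- sort(unique(r$dhc_normalized))
  purrr::map_dfr(cand, function(c) {
    keep <- r$dhc_normalized >= c
    tibble::tibble(
      cutoff = c,
      n_retained = sum(keep),
      retained_accuracy = mean(r$call[keep] == r$manual_label[keep]),
      discard_fraction = mean(!keep)
    )
  })
}

#' Confidence-map data for plotting
#'
#' Per label, records sorted by DHC score with their rank and correctness —
#' the data behind the confidence maps with green (correct) and red
#' (incorrect) dots.
#'
#' @inheritParams rank_by_dhc
#' @return Tibble: `cell_type`, `rank`, `image_id`, `dhc_normalized`,
#'   `correct`.
#' @export
confidence_map_data <- function(records, label = NULL) {
  labels <- label %||% unique(records$cell_type)
  purrr::map_dfr(labels, function(l) {
    r <- label_records(records, l)
    r <- r[order(r$dhc_normalized, r$image_id), ]
    tibble::tibble(
      cell_type = l,
      rank = seq_len(nrow(r)),
      image_id = r$image_id,
      dhc_normalized = r$dhc_normalized,
      correct = r$call == r$manual_label
    )
  })
}
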