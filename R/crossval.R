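# One repetition of iterative stratification: examples carrying the
# currently rarest label are distributed first, to the eligible fold with
# the largest remaining per-label quota (ties: largest remaining capacity,
# then the seeded generator). Fold sizes are constrained to differ by at
# most one: at most (n mod k) folds may exceed floor(n/k).
stratify_once <- function(Y, n_folds) {
  n <- nrow(Y)
  C <- ncol(Y)
  fold_of <- integer(n)
  base <- n %/% n_folds
  extra <- n %% n_folds
  sizes <- integer(n_folds)
  quota <- matrix(rep(colSums(Y) / n_folds, each = n_folds), n_folds, C)
  remaining <- rep(TRUE, n)
  eligible <- function() sizes < base | (sizes == base & extra > 0L)
  assign_to <- function(f, i) {
    if (sizes[f] == base) extra <<- extra - 1L
    sizes[f] <<- sizes[f] + 1L
    fold_of[i] <<- f
    remaining[i] <<- FALSE
  }
  while (any(remaining)) {
    counts <- colSums(Y[remaining, , drop = FALSE])
    active <- which(counts > 0)
    if (length(active) == 0L) {
      for (i in which(remaining)) {
        ok <- which(eligible())
        f <- ok[pick_max(base + (extra > 0L) - sizes[ok])]
        assign_to(f, i)
      }
      break
    }
    lab <- active[which.min(counts[active])]
    idx <- which(remaining & Y[, lab] == 1)
    idx <- idx[sample.int(length(idx))] # seeded randomisation within the label
    for (i in idx) {
      labs_i <- which(Y[i, ] == 1)
      ok <- which(eligible())
      top <- ok[quota[ok, lab] == max(quota[ok, lab])]
      if (length(top) > 1L) {
        # secondary key: remaining quota across all of this example's labels
        k2 <- rowSums(quota[top, labs_i, drop = FALSE])
        top <- top[k2 == max(k2)]
      }
      f <- top[pick_max(-sizes[top])]
      assign_to(f, i)
      quota[f, labs_i] <- quota[f, labs_i] - 1
    }
  }
  fold_of
}

pick_max <- function(score, tiebreak = NULL) {
  top <- which(score == max(score))
  if (length(top) > 1L && !is.null(tiebreak)) {
    top <- top[tiebreak[top] == max(tiebreak[top])]
  }
  if (length(top) > 1L) top <- top[sample.int(length(top), 1L)]
  top
}

#' Multilabel stratified k-fold split plan
#'
#' Repeated k-fold assignment by iterative stratification: folds preserve
#' the per-label positive fraction, with fresh randomisation in each
#' repetition. When `groups` is supplied (e.g. antibody ids, so the 1-3
#' images of one antibody never straddle folds), whole groups are assigned,
#' a group counting as positive for a label if any member is.
#'
#' @param Y `n x C` binary label matrix (rownames used as ids when present).
#' @param n_folds Number of folds (>= 2, <= n).
#' @param n_repeats Number of independently randomised repetitions.
#' @param seed Seed for the assignment randomisation.
#' @param groups Optional length-n grouping vector.
#' @return A tibble with class `"ihc_split_plan"`: `id`, `repetition`,
#'   `fold`.
#' @export
multilabel_stratified_split <- function(Y, n_folds = 10L, n_repeats = 10L,
                                        seed = 1L, groups = NULL) {
  Y <- as.matrix(Y)
  n <- nrow(Y)
  if (n_folds < 2L) stop("n_folds must be >= 2", call. = FALSE)
  if (n < n_folds) stop("need at least n_folds = ", n_folds, " examples", call. = FALSE)
  ids <- rownames(Y) %||% as.character(seq_len(n))
  set.seed(seed)
  if (!is.null(groups)) {
    stopifnot(length(groups) == n)
    gl <- split(seq_len(n), groups)
    Yg <- t(vapply(gl, function(ix) {
      as.integer(colSums(Y[ix, , drop = FALSE]) > 0)
    }, integer(ncol(Y))))
  }
  plans <- purrr::map(seq_len(n_repeats), function(rep_i) {
    if (is.null(groups)) {
      fold_of <- stratify_once(Y, n_folds)
    } else {
      gf <- stratify_once(Yg, n_folds)
      fold_of <- integer(n)
      for (g in seq_along(gl)) fold_of[gl[[g]]] <- gf[g]
    }
    tibble::tibble(id = ids, repetition = rep_i, fold = fold_of)
  })
  out <- dplyr::bind_rows(plans)
  class(out) <- unique(c("ihc_split_plan", class(out)))
  out
}

#' Per-fold prevalence gap of a split plan
#'
#' Largest absolute difference between a fold's per-label positive fraction
#' and the global one, per repetition and label — the quality measure of the
#' stratification.
#'
#' @param plan A plan from [multilabel_stratified_split()].
#' @param Y The label matrix the plan was built from.
#' @return Tibble: `repetition`, `fold`, `label`, `prevalence`, `gap`.
#' @export
split_prevalence_gaps <- function(plan, Y) {
  Y <- as.matrix(Y)
  ids <- rownames(Y) %||% as.character(seq_len(nrow(Y)))
  labels <- colnames(Y) %||% paste0("label_", seq_len(ncol(Y)))
  global <- colMeans(Y)
  plan |>
    dplyr::group_by(.data$repetition, .data$fold) |>
    dplyr::reframe(
      label = labels,
      prevalence = colMeans(Y[match(.data$id, ids), , drop = FALSE]),
      gap = abs(.data$prevalence - global)
    )
}

#' Mean and standard deviation of a per-fold metric
#'
#' Sample mean and (n-1)-denominator standard deviation across
#' cross-validation folds, as reported next to fold-level accuracies.
#'
#' @param metric_per_fold Numeric vector, length >= 2.
#' @return Named list with `mean` and `std`.
#' @export
fold_variance_report <- function(metric_per_fold) {
  if (length(metric_per_fold) < 2L) stop("need at least 2 fold values", call. = FALSE)
  list(mean = mean(metric_per_fold), std = stats::sd(metric_per_fold))
}

#' Write / read a split plan as TSV
#'
#' @param plan An `"ihc_split_plan"`.
#' @param path Output path.
#' @return `path` invisibly / the plan tibble.
#' @export
write_split_plan <- function(plan, path) {
  readr::write_tsv(plan, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_split_plan
#' @export
read_split_plan <- function(path) {
  out <- readr::read_tsv(path,
    col_types = readr::cols(
      id = readr::col_character(),
      repetition = readr::col_integer(),
      fold = readr::col_integer()
    ),
    progress = FALSE
  )
  class(out) <- unique(c("ihc_split_plan", class(out)))
  out
}
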