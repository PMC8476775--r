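#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a trained hybrid network
#'
#' Returns the per-epoch training log as a tibble.
#'
#' @param x A trained `"hbnet"`.
#' @param ... Unused.
#' @return Tibble with `epoch`, `loss`, `val_accuracy`.
#' @export
tidy.hbnet <- function(x, ...) {
  if (is.null(x$log)) stop("model has not been trained", call. = FALSE)
  x$log
}

#' @rdname tidy.hbnet
#' @export
glance.hbnet <- function(x, ...) {
  cfg <- x$config
  tibble::tibble(
    backbone = cfg$backbone,
    input_side = cfg$input_side,
    n_labels = cfg$n_labels,
    drop_weight_rate = cfg$drop_weight_rate,
    epochs_run = if (is.null(x$log)) 0L else nrow(x$log),
    best_epoch = x$best_epoch %||% NA_integer_,
    best_val_accuracy = x$best_val_accuracy %||% NA_real_
  )
}

#' Tidy an evaluation report
#'
#' @param x An `"ihc_evaluation"`.
#' @param ... Unused.
#' @return The per-label confusion tibble.
#' @export
tidy.ihc_evaluation <- function(x, ...) x$per_label

#' @rdname tidy.ihc_evaluation
#' @export
glance.ihc_evaluation <- function(x, ...) {
  tibble::tibble(
    n = x$n,
    hamming_loss = x$hamming_loss,
    macro_f1 = x$macro_f1,
    micro_f1 = x$micro_f1,
    exact_match = x$exact_match,
    mean_average_precision = x$mean_average_precision
  )
}

#' Tidy a triage result
#'
#' @param x An `"ihc_triage"`.
#' @param ... Unused.
#' @return The per-label triage summary tibble.
#' @export
tidy.ihc_triage <- function(x, ...) x$summary

#' @rdname tidy.ihc_triage
#' @export
glance.ihc_triage <- function(x, ...) {
  s <- x$summary
  tibble::tibble(
    n_labels = nrow(s),
    mean_overall_accuracy = mean(s$overall_accuracy),
    mean_retained_accuracy = mean(s$retained_accuracy, na.rm = TRUE),
    mean_discard_fraction = mean(s$discard_fraction)
  )
}

#' Tidy a study result
#'
#' @param x An `"ihc_study"`.
#' @param ... Unused.
#' @return Per-label tibble joining evaluation and triage columns.
#' @export
tidy.ihc_study <- function(x, ...) {
  dplyr::left_join(
    tidy(x$evaluation), tidy(x$triage),
    by = "cell_type"
  )
}

#' @rdname tidy.ihc_study
#' @export
glance.ihc_study <- function(x, ...) {
  dplyr::bind_cols(
    glance(x$evaluation),
    glance(x$triage)[c("mean_overall_accuracy", "mean_retained_accuracy", "mean_discard_fraction")],
    tibble::tibble(chance_exact_match = x$chance_exact_match)
  )
}
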