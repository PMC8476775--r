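#' Confidence-map plot
#'
#' Predictions per cell type sorted by DHC score: green dots where model and
#' manual annotation agree, red where they disagree, with a blue vertical
#' line at each label's triage cutoff.
#'
#' @param records An `"ihc_uncertainty"` tibble with manual labels.
#' @param cutoffs Optional named per-label cutoff vector to draw.
#' @return A ggplot object.
#' @export
plot_confidence_map <- function(records, cutoffs = NULL) {
  dat <- confidence_map_data(records)
  p <- ggplot2::ggplot(
    dat,
    ggplot2::aes(x = .data$rank, y = .data$dhc_normalized, colour = .data$correct)
  ) +
    ggplot2::geom_point(size = 0.6, alpha = 0.8) +
    ggplot2::scale_colour_manual(
      values = c(`TRUE` = "#2e7d32", `FALSE` = "#c62828"),
      labels = c(`TRUE` = "correct", `FALSE` = "incorrect"),
      name = NULL
    ) +
    ggplot2::facet_wrap(ggplot2::vars(.data$cell_type), scales = "free_x") +
    ggplot2::labs(
      x = "prediction rank (ascending DHC)",
      y = "normalised DHC score"
    ) +
    ggplot2::theme_minimal()
  if (!is.null(cutoffs)) {
    cut_df <- tibble::tibble(
      cell_type = names(cutoffs), cutoff = as.numeric(cutoffs)
    )
    p <- p + ggplot2::geom_hline(
      data = cut_df,
      ggplot2::aes(yintercept = .data$cutoff),
      colour = "#1565c0", linewidth = 0.4
    )
  }
  p
}

#' Accuracy versus discard trade-off plot
#'
#' @param records An `"ihc_uncertainty"` tibble with manual labels.
#' @param labels Cell types to include (default all).
#' @return A ggplot object.
#' @export
plot_accuracy_discard <- function(records, labels = NULL) {
  labels <- labels %||% unique(records$cell_type)
  dat <- purrr::map_dfr(labels, function(l) {
    dplyr::mutate(accuracy_discard_curve(records, l), cell_type = l)
  })
  ggplot2::ggplot(
    dat,
    ggplot2::aes(x = .data$discard_fraction, y = .data$retained_accuracy)
  ) +
    ggplot2::geom_step() +
    ggplot2::facet_wrap(ggplot2::vars(.data$cell_type)) +
    ggplot2::labs(x = "fraction discarded", y = "retained accuracy") +
    ggplot2::theme_minimal()
}

#' Cell-type Kendall correlation heatmap
#'
#' @param K Correlation matrix from [kendall_label_correlation()].
#' @return A ggplot object.
#' @export
plot_label_correlation <- function(K) {
  dat <- tibble::tibble(
    a = rep(rownames(K), times = ncol(K)),
    b = rep(colnames(K), each = nrow(K)),
    tau = as.vector(K)
  )
  dat$a <- factor(dat$a, levels = rownames(K))
  dat$b <- factor(dat$b, levels = colnames(K))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$a, y = .data$b, fill = .data$tau)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(
      low = "#2166ac", mid = "white", high = "#b2182b", limits = c(-1, 1)
    ) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Kendall tau") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Training curve plot
#'
#' @param model A trained `"hbnet"`.
#' @return A ggplot object.
#' @export
plot_training_log <- function(model) {
  stopifnot(inherits(model, "hbnet"), !is.null(model$log))
  dat <- tidyr::pivot_longer(model$log, c("loss", "val_accuracy"),
    names_to = "metric", values_to = "value"
  )
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(ggplot2::vars(.data$metric), scales = "free_y") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.ihc_uncertainty <- function(object, ...) plot_confidence_map(object, ...)

#' @export
autoplot.ihc_triage <- function(object, ...) {
  dat <- tidyr::pivot_longer(object$summary,
    c("overall_accuracy", "retained_accuracy"),
    names_to = "kind", values_to = "accuracy"
  )
  ggplot2::ggplot(
    dat,
    ggplot2::aes(x = .data$cell_type, y = .data$accuracy, fill = .data$kind)
  ) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "per-label accuracy", fill = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.hbnet <- function(object, ...) plot_training_log(object)
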