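#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an ROC curve
#'
#' @param object A `keap_roc` tibble from [roc_curve()].
#' @param ... Unused.
#' @return A ggplot: the empirical ROC staircase with the chance diagonal,
#'   AUC in the subtitle.
#' @export
autoplot.keap_roc <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(linewidth = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "False positive rate (1 - specificity)",
      y = "True positive rate (sensitivity)",
      subtitle = sprintf("AUC = %.3f (%d positive / %d negative)",
                         attr(object, "auc"), attr(object, "n_pos"),
                         attr(object, "n_neg"))
    ) +
    ggplot2::theme_minimal()
}

#' Plot benchmark Youden's J by test and stratum
#'
#' Bar chart of validation Youden's J for every evaluated test, faceted by
#' reference label and stratum -- the package's analogue of a benchmark
#' overview figure.
#'
#' @param reports Performance reports from [evaluate_suite()] or a bundle's
#'   `reports.tsv`; screening-stage rows are dropped (only final tests are
#'   shown).
#' @return A ggplot.
#' @export
plot_youden <- function(reports) {
  if (!"youden_j" %in% names(reports)) {
    abort("`reports` does not look like a performance report table.")
  }
  d <- reports
  if ("status" %in% names(d)) d <- d[!is.na(d$status) & d$status == "ok", ]
  if ("stage" %in% names(d)) d <- d[is.na(d$stage) | d$stage != "screen", ]
  if (!"reference_label" %in% names(d)) d$reference_label <- d$reference
  d$test <- paste0(d$marker, " (", d$objective, ")")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$youden_j, y = .data$test,
                                  fill = .data$type)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_grid(ggplot2::vars(.data$reference_label),
                        ggplot2::vars(.data$stratum)) +
    ggplot2::labs(x = "Youden's J (validation)", y = NULL, fill = NULL) +
    ggplot2::xlim(min(0, min(d$youden_j, na.rm = TRUE)), 1) +
    ggplot2::theme_minimal()
}
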