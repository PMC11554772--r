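#' Tidy a cutpoint fit
#'
#' @param x A `cutpoint_fit` from [cut_youden()] or [cut_screening()].
#' @param ... Unused.
#' @return One-row tibble with `cutpoint`, `direction`, `sensitivity`,
#'   `specificity`, `youden_j`, `objective`, `min_specificity`.
#' @export
tidy.cutpoint_fit <- function(x, ...) {
  tibble(
    cutpoint = x$cutpoint, direction = x$direction,
    sensitivity = x$sensitivity, specificity = x$specificity,
    youden_j = x$youden_j, objective = x$objective,
    min_specificity = x$min_specificity
  )
}

#' Glance at a cutpoint fit
#'
#' @inheritParams tidy.cutpoint_fit
#' @return One-row tibble with the training-data summary: `auc`, `n_pos`,
#'   `n_neg`, `youden_j`.
#' @export
glance.cutpoint_fit <- function(x, ...) {
  tibble(auc = x$auc, n_pos = x$n_pos, n_neg = x$n_neg,
         youden_j = x$youden_j)
}

#' Tidy a test rule
#'
#' @param x A [test_rule()].
#' @param ... Unused.
#' @return One-row tibble with `marker`, `cutpoint`, `direction`.
#' @export
tidy.test_rule <- function(x, ...) {
  tibble(marker = x$marker, cutpoint = x$cutpoint, direction = x$direction)
}

#' Tidy a combined rule
#'
#' @param x A [combined_rule()].
#' @param ... Unused.
#' @return Two-row tibble (stages `screen` and `validate`) with `marker`,
#'   `cutpoint`, `direction`.
#' @export
tidy.combined_rule <- function(x, ...) {
  bind_rows(
    mutate(tidy(x$screen), stage = "screen"),
    mutate(tidy(x$validator), stage = "validate")
  )
}
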