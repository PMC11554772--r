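#' Single-marker test rules
#'
#' A test rule is a thresholded single-marker classifier: a marker (panel
#' gene symbol, `"h_score"`, `"k1n2_score"` or `"k1n2_call"`), a cutpoint
#' and a direction, optionally tagged with a training descriptor. A sample
#' is called positive per the [apply_cutpoint()] convention.
#'
#' @param marker Column name the score is read from.
#' @param cutpoint Threshold value (may be `-Inf`/`+Inf` sentinels).
#' @param direction `"greater"` (default) or `"less"`.
#' @param trained_on Optional descriptor list (stratum, objective,
#'   constraint) recorded for provenance.
#' @return A `test_rule` object.
#' @export
test_rule <- function(marker, cutpoint, direction = c("greater", "less"),
                      trained_on = NULL) {
  direction <- arg_match(direction)
  if (!is.character(marker) || length(marker) != 1) {
    abort("`marker` must be a single column name.")
  }
  if (!is.numeric(cutpoint) || length(cutpoint) != 1 || is.na(cutpoint)) {
    abort("`cutpoint` must be a single non-missing number.")
  }
  structure(
    list(marker = marker, cutpoint = cutpoint, direction = direction,
         trained_on = trained_on),
    class = "test_rule"
  )
}

#' Turn a cutpoint fit into a deployable test rule
#'
#' @param fit A `cutpoint_fit` from [cut_youden()] or [cut_screening()].
#' @param marker Column name the fit was trained on.
#' @param trained_on Optional training descriptor; defaults to the fit's
#'   objective and constraint.
#' @return A [test_rule()].
#' @export
as_test_rule <- function(fit, marker, trained_on = NULL) {
  if (!inherits(fit, "cutpoint_fit")) abort("`fit` must be a cutpoint_fit.")
  trained_on <- trained_on %||%
    list(objective = fit$objective, min_specificity = fit$min_specificity)
  test_rule(marker, fit$cutpoint, fit$direction, trained_on = trained_on)
}

#' Two-stage screen-then-validate rule
#'
#' AND-composition of a cheap, sensitivity-optimized screening rule with a
#' fixed high-accuracy validator (the K1N2 rule): screen-positive samples
#' are forwarded to the validator, screen-negatives are final-negative
#' without consuming the validator. The validator is fixed input -- its
#' cutoff is taken over, never refit here.
#'
#' @param screen A [test_rule()] trained with the screening objective.
#' @param validator A [test_rule()], typically [k1n2_rule()].
#' @return A `combined_rule` object.
#' @export
combined_rule <- function(screen, validator) {
  if (!inherits(screen, "test_rule") || !inherits(validator, "test_rule")) {
    abort("`screen` and `validator` must be test_rule objects.")
  }
  structure(list(screen = screen, validator = validator),
            class = "combined_rule")
}

#' The K1N2 validator rule
#'
#' The 46-gene signature score is consumed as given, either through its
#' published binary pathway call (`cutoff = NULL`, the default: the rule
#' reads the `k1n2_call` column) or as the continuous `k1n2_score` with a
#' fixed externally supplied cutoff. It is never trained by this package.
#'
#' @param cutoff `NULL` for the published-call passthrough, or a fixed
#'   numeric cutoff applied to `k1n2_score`.
#' @return A [test_rule()].
#' @export
k1n2_rule <- function(cutoff = NULL) {
  if (is.null(cutoff)) {
    test_rule("k1n2_call", 0.5, "greater",
              trained_on = list(objective = "published_call"))
  } else {
    test_rule("k1n2_score", cutoff, "greater",
              trained_on = list(objective = "fixed_cutoff"))
  }
}

#' Youden's J index
#'
#' @param sensitivity,specificity Proportions in \[0, 1\] (vectorized).
#' @return `sensitivity + specificity - 1`, in \[-1, 1\].
#' @export
#' @examples
#' youden_j(0.87, 0.87) # 0.74
youden_j <- function(sensitivity, specificity) {
  ok <- function(x) is.numeric(x) && all(!is.na(x) & x >= 0 & x <= 1)
  if (!ok(sensitivity) || !ok(specificity)) {
    abort("sensitivity and specificity must be proportions in [0, 1].")
  }
  sensitivity + specificity - 1
}

marker_scores <- function(cohort, marker) {
  if (!marker %in% names(cohort)) {
    abort(paste0("Cohort has no column '", marker, "'."))
  }
  v <- cohort[[marker]]
  if (is.logical(v)) v <- as.numeric(v)
  if (!is.numeric(v)) {
    abort(paste0("Marker column '", marker, "' is not numeric."))
  }
  v
}

confusion_row <- function(calls, labels) {
  tp <- sum(calls & labels)
  fp <- sum(calls & !labels)
  tn <- sum(!calls & !labels)
  fn <- sum(!calls & labels)
  tibble(
    tp = tp, fp = fp, tn = tn, fn = fn,
    sensitivity = tp / (tp + fn),
    specificity = tn / (tn + fp),
    youden_j = tp / (tp + fn) + tn / (tn + fp) - 1,
    n_evaluated = length(calls)
  )
}

#' Evaluate a single-marker test on a cohort
#'
#' Applies a trained rule to every sample carrying both the marker and the
#' reference label (samples missing either are dropped and counted, never
#' imputed -- mirroring real cohorts where IHC and RNA denominators
#' differ), and reports the confusion counts and derived metrics.
#'
#' @param cohort A cohort tibble (typically a validation subset).
#' @param rule A [test_rule()] or `cutpoint_fit` with a `marker` attached
#'   via [as_test_rule()].
#' @param reference Reference label; see [reference_label()].
#' @param stratum Optional descriptor string recorded in the report.
#' @return One-row tibble: `marker`, `cutpoint`, `direction`, `stratum`,
#'   `reference`, `tp`, `fp`, `tn`, `fn`, `sensitivity`, `specificity`,
#'   `youden_j`, `n_evaluated`, `n_dropped_missing`.
#' @export
evaluate_test <- function(cohort, rule, reference = "mutation_status",
                          stratum = NA_character_) {
  if (!inherits(rule, "test_rule")) {
    abort("`rule` must be a test_rule (see as_test_rule()).")
  }
  scores <- marker_scores(cohort, rule$marker)
  labels <- reference_label(cohort, reference)
  keep <- !is.na(scores) & !is.na(labels)
  n_dropped <- sum(!keep)
  scores <- scores[keep]
  labels <- labels[keep]
  if (length(scores) == 0) {
    abort("No samples carry both the marker and the reference label.")
  }
  if (sum(labels) == 0 || sum(!labels) == 0) {
    abort(paste0("Evaluation undefined for marker '", rule$marker,
                 "': cohort has no ",
                 if (sum(labels) == 0) "positive" else "negative",
                 " samples after dropping missing values."))
  }
  calls <- apply_cutpoint(scores, rule)
  out <- confusion_row(calls, labels)
  dplyr::bind_cols(
    tibble(marker = rule$marker, cutpoint = rule$cutpoint,
           direction = rule$direction, stratum = stratum,
           reference = reference),
    out,
    tibble(n_dropped_missing = n_dropped)
  )
}

#' Evaluate a two-stage screen-then-validate test
#'
#' Final call = screen-positive AND validator-positive; screen-negative
#' samples are final-negative and never consume the validator. Samples must
#' carry the screen marker, the validator marker and the reference label;
#' others are dropped and counted. Both the screening-stage report and the
#' final report are returned.
#'
#' @param cohort A cohort tibble.
#' @param rule A [combined_rule()].
#' @inheritParams evaluate_test
#' @return Two-row tibble (rows `stage = "screen"` and `stage =
#'   "combined"`) with the columns of [evaluate_test()] plus `stage` and
#'   `n_validated` (screen-positives forwarded to the validator).
#' @export
evaluate_combined <- function(cohort, rule, reference = "mutation_status",
                              stratum = NA_character_) {
  if (!inherits(rule, "combined_rule")) {
    abort("`rule` must be a combined_rule.")
  }
  s_scores <- marker_scores(cohort, rule$screen$marker)
  v_scores <- marker_scores(cohort, rule$validator$marker)
  labels <- reference_label(cohort, reference)
  keep <- !is.na(s_scores) & !is.na(v_scores) & !is.na(labels)
  n_dropped <- sum(!keep)
  s_scores <- s_scores[keep]
  v_scores <- v_scores[keep]
  labels <- labels[keep]
  if (length(labels) == 0 || sum(labels) == 0 || sum(!labels) == 0) {
    abort("Combined evaluation undefined: need both classes after dropping.")
  }
  screen_calls <- apply_cutpoint(s_scores, rule$screen)
  final_calls <- rep(FALSE, length(screen_calls))
  if (any(screen_calls)) { # validator consumed only by screen-positives
    final_calls[screen_calls] <-
      apply_cutpoint(v_scores[screen_calls], rule$validator)
  }
  mk_row <- function(stage, calls, marker, cutpoint, direction) {
    dplyr::bind_cols(
      tibble(stage = stage, marker = marker, cutpoint = cutpoint,
             direction = direction, stratum = stratum, reference = reference),
      confusion_row(calls, labels),
      tibble(n_dropped_missing = n_dropped,
             n_validated = sum(screen_calls))
    )
  }
  bind_rows(
    mk_row("screen", screen_calls, rule$screen$marker,
           rule$screen$cutpoint, rule$screen$direction),
    mk_row("combined", final_calls,
           paste0(rule$screen$marker, "+", rule$validator$marker),
           rule$screen$cutpoint, rule$screen$direction)
  )
}

#' Fraction of samples spared K1N2 testing
#'
#' In the two-stage algorithm every sample is screened but only
#' screen-positives undergo the expensive 46-gene panel; the reduction is
#' the fraction of evaluable samples that are screen-negative, relative to
#' testing everyone. By construction `k1n2_reduction + (fraction forwarded
#' to validation) = 1`.
#'
#' @param cohort A cohort tibble.
#' @param rule A [combined_rule()] or the screening [test_rule()] itself.
#' @return Proportion in \[0, 1\].
#' @export
k1n2_reduction <- function(cohort, rule) {
  screen <- if (inherits(rule, "combined_rule")) rule$screen else rule
  if (!inherits(screen, "test_rule")) {
    abort("`rule` must be a combined_rule or test_rule.")
  }
  scores <- marker_scores(cohort, screen$marker)
  scores <- scores[!is.na(scores)]
  if (length(scores) == 0) {
    abort("No samples carry the screening marker.")
  }
  mean(!apply_cutpoint(scores, screen))
}

#' Train the full benchmark test suite
#'
#' For every marker x stratum (LUAD, LUSC, pooled) x objective, fits the
#' cutpoint on the `use` subset only -- never touching validation labels --
#' and emits a deployable rule tagged with its training descriptor.
#' Screening-objective rules are additionally composed with the fixed K1N2
#' validator into two-stage rules, and the validator itself is carried
#' through unchanged as a comparator per stratum. Failures (e.g. an
#' infeasible screening constraint or a single-class stratum) are isolated:
#' the affected row gets `status = "error"` and the message, other rows
#' proceed.
#'
#' @param cohort A cohort tibble with a populated split (see
#'   [split_cohort()]).
#' @param markers Character vector of marker columns to train on.
#' @param objectives Subset of `c("youden", "screening")`.
#' @param reference Reference label used for training; see
#'   [reference_label()].
#' @param min_specificity Specificity floor for the screening objective
#'   (default 0.3).
#' @param validator The fixed validator rule; default [k1n2_rule()]
#'   (published-call passthrough).
#' @param strata Strata to train in; default `c("LUAD", "LUSC", "pooled")`.
#' @param direction Score direction passed to the optimizers.
#' @return Tibble with one row per trained rule: `marker`, `stratum`,
#'   `objective`, `type` (`single` / `combined` / `validator`), `cutpoint`,
#'   `direction`, `train_sensitivity`, `train_specificity`, `train_j`,
#'   `status`, `message`, and a `rule` list-column of deployable rule
#'   objects.
#' @export
train_test_suite <- function(cohort, markers,
                             objectives = c("youden", "screening"),
                             reference = "mutation_status",
                             min_specificity = 0.3,
                             validator = k1n2_rule(),
                             strata = c("LUAD", "LUSC", "pooled"),
                             direction = "greater") {
  objectives <- arg_match(objectives,
                          values = c("youden", "screening"), multiple = TRUE)
  if (!"split_group" %in% names(cohort) || all(is.na(cohort$split_group))) {
    abort("Cohort has no populated split; call split_cohort() first.")
  }
  grid <- tidyr::expand_grid(stratum = strata, marker = markers,
                             objective = objectives)
  rows <- pmap(grid, function(stratum, marker, objective) {
    train <- subset_cohort(
      cohort,
      histology = if (stratum == "pooled") NULL else stratum,
      split_group = "use"
    )
    train$..label <- reference_label(train, reference)
    train <- train[!is.na(train[[marker]]) & !is.na(train$..label), ,
                   drop = FALSE]
    fit <- tryCatch(
      {
        if (objective == "youden") {
          cut_youden(train, !!sym(marker), .data$..label,
                     direction = direction)
        } else {
          cut_screening(train, !!sym(marker), .data$..label,
                        direction = direction,
                        min_specificity = min_specificity)
        }
      },
      error = function(e) e
    )
    if (inherits(fit, "error")) {
      return(tibble(
        marker = marker, stratum = stratum, objective = objective,
        type = "single", cutpoint = NA_real_, direction = direction,
        train_sensitivity = NA_real_, train_specificity = NA_real_,
        train_j = NA_real_, status = "error",
        message = conditionMessage(fit), rule = list(NULL)
      ))
    }
    single <- as_test_rule(
      fit, marker,
      trained_on = list(stratum = stratum, objective = fit$objective,
                        min_specificity = fit$min_specificity,
                        reference = reference)
    )
    out <- tibble(
      marker = marker, stratum = stratum, objective = objective,
      type = "single", cutpoint = fit$cutpoint, direction = fit$direction,
      train_sensitivity = fit$sensitivity,
      train_specificity = fit$specificity,
      train_j = fit$youden_j, status = "ok", message = NA_character_,
      rule = list(single)
    )
    if (objective == "screening") {
      out <- bind_rows(out, mutate(out, type = "combined",
                                   rule = list(combined_rule(single,
                                                             validator))))
    }
    out
  })
  suite <- list_rbind(rows)
  validator_rows <- tibble(
    marker = validator$marker, stratum = strata, objective = "fixed",
    type = "validator", cutpoint = validator$cutpoint,
    direction = validator$direction,
    train_sensitivity = NA_real_, train_specificity = NA_real_,
    train_j = NA_real_, status = "ok", message = NA_character_,
    rule = lapply(strata, function(s) validator)
  )
  bind_rows(suite, validator_rows)
}

#' Evaluate a trained suite on a cohort subset
#'
#' Applies every successfully trained rule to the matching evaluation
#' subset (histology-specific rules within their histology, pooled rules
#' cohort-wide) and binds the performance reports. Two-stage rules
#' additionally report the K1N2-testing reduction. Evaluation failures are
#' isolated per rule (`status = "error"`).
#'
#' @param cohort The full split cohort.
#' @param suite Output of [train_test_suite()].
#' @param reference Reference label for evaluation (defaults to the
#'   training choice is the caller's responsibility; pass explicitly).
#' @param split_group Which split to evaluate on; default `"validation"`.
#' @return Tibble of performance reports, one row per rule (two for
#'   combined rules: screen stage and final), with `k1n2_reduction` filled
#'   for combined rules.
#' @export
evaluate_suite <- function(cohort, suite, reference = "mutation_status",
                           split_group = "validation") {
  rows <- pmap(
    list(suite$marker, suite$stratum, suite$objective, suite$type,
         suite$status, suite$rule),
    function(marker, stratum, objective, type, status, rule) {
      base <- tibble(marker = marker, stratum = stratum,
                     objective = objective, type = type)
      if (status != "ok" || is.null(rule)) {
        return(mutate(base, status = "not_trained"))
      }
      eval_data <- subset_cohort(
        cohort,
        histology = if (stratum == "pooled") NULL else stratum,
        split_group = split_group
      )
      rep <- tryCatch(
        {
          if (inherits(rule, "combined_rule")) {
            r <- evaluate_combined(eval_data, rule, reference = reference,
                                   stratum = stratum)
            r$k1n2_reduction <- c(NA_real_,
                                  k1n2_reduction(eval_data, rule))
            r
          } else {
            r <- evaluate_test(eval_data, rule, reference = reference,
                               stratum = stratum)
            r$stage <- "single"
            r
          }
        },
        error = function(e) e
      )
      if (inherits(rep, "error")) {
        return(mutate(base, status = "error",
                      message = conditionMessage(rep)))
      }
      rep$marker <- NULL # keep the suite's marker/stratum naming
      rep$stratum <- NULL
      dplyr::bind_cols(base, rep, tibble(status = "ok"))
    }
  )
  out <- list_rbind(rows)
  if ("stage" %in% names(out)) {
    out <- dplyr::relocate(out, dplyr::any_of("stage"),
                           .after = "type")
  }
  out
}
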