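#' ROC curves and cutpoint optimization
#'
#' All thresholded tests in the benchmark use the same candidate-cutpoint
#' rule: midpoints between consecutive sorted distinct observed scores, plus
#' `-Inf` / `+Inf` sentinels. This set is finite, complete (every achievable
#' confusion table is represented) and stable under monotone transforms of
#' the data ranks. A sample is called positive iff its score is `>=` the
#' cutpoint (direction `"greater"`) or `<=` it (direction `"less"`).
#'
#' @name roc-cutpoint
NULL

# --- internal vector engine (direction already normalized to "greater") ----

check_scored_labels <- function(scores, labels) {
  if (length(scores) != length(labels)) {
    abort("`scores` and labels must have equal length.")
  }
  if (length(scores) < 1) abort("Empty score vector.")
  if (any(!is.finite(scores))) {
    abort("Scores must be finite (drop missing values before scoring).")
  }
  if (any(is.na(labels))) abort("Labels must not be missing.")
  if (sum(labels) == 0 || sum(!labels) == 0) {
    abort(paste0("ROC undefined: need at least one positive and one ",
                 "negative sample (got ", sum(labels), " positive of ",
                 length(labels), ")."))
  }
  invisible(TRUE)
}

# confusion table at every candidate cutpoint, descending cutpoint order:
# +Inf (call nobody), midpoints between distinct scores, -Inf (call everyone)
roc_candidates <- function(scores, labels) {
  np <- sum(labels)
  nn <- sum(!labels)
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]
  y <- labels[o]
  d <- unique(s) # descending distinct values
  grp <- match(s, d)
  last <- which(diff(c(grp, Inf)) != 0) # last index of each tie group
  tp <- c(0, cumsum(y)[last])
  fp <- c(0, cumsum(!y)[last])
  K <- length(d)
  mids <- if (K > 1) (d[-K] + d[-1]) / 2 else numeric(0)
  tibble(
    cutpoint = c(Inf, mids, -Inf),
    tp = tp, fp = fp,
    sensitivity = tp / np,
    specificity = (nn - fp) / nn
  )
}

trapezoid_auc <- function(fpr, tpr) {
  sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
}

# midrank (Mann-Whitney) AUC; identical to the trapezoid by the standard
# tie-as-half-credit identity -- used where many AUCs are needed (bootstrap)
rank_auc <- function(scores, labels) {
  np <- sum(labels)
  nn <- sum(!labels)
  (mean(rank(scores)[labels]) - (np + 1) / 2) / nn
}

normalize_direction <- function(scores, direction) {
  if (direction == "greater") scores else -scores
}

# map an internal ("greater"-space) cutpoint back to the original scale
denormalize_cutpoint <- function(cutpoint, direction) {
  if (direction == "greater") cutpoint else -cutpoint
}

extract_scored <- function(data, score, truth) {
  sc <- eval_tidy(score, data)
  lb <- eval_tidy(truth, data)
  if (!is.numeric(sc)) abort("The score column must be numeric.")
  list(scores = as.numeric(sc), labels = as.logical(lb))
}

# --- exported, data-frame-first API ----------------------------------------

#' Empirical ROC curve
#'
#' @param data Data frame with one row per sample.
#' @param score Unquoted column holding the continuous marker value.
#' @param truth Unquoted column holding the binary reference label
#'   (logical, or coercible; `TRUE` = positive class).
#' @param direction `"greater"` if higher scores indicate the positive
#'   class (the default throughout: NFE2L2 target genes are upregulated on
#'   pathway activation), `"less"` otherwise.
#' @return A tibble of class `keap_roc` with columns `cutpoint`, `fpr`,
#'   `tpr` ordered from (0,0) to (1,1); attributes `auc`, `n_pos`, `n_neg`,
#'   `direction`.
#' @export
#' @examples
#' d <- tibble::tibble(x = c(3, 5, 1, 4), y = c(TRUE, TRUE, FALSE, FALSE))
#' roc_curve(d, x, y)
roc_curve <- function(data, score, truth, direction = c("greater", "less")) {
  direction <- arg_match(direction)
  sl <- extract_scored(data, enquo(score), enquo(truth))
  check_scored_labels(sl$scores, sl$labels)
  cand <- roc_candidates(normalize_direction(sl$scores, direction), sl$labels)
  out <- tibble(
    cutpoint = denormalize_cutpoint(cand$cutpoint, direction),
    fpr = 1 - cand$specificity,
    tpr = cand$sensitivity
  )
  attr(out, "auc") <- trapezoid_auc(out$fpr, out$tpr)
  attr(out, "n_pos") <- sum(sl$labels)
  attr(out, "n_neg") <- sum(!sl$labels)
  attr(out, "direction") <- direction
  class(out) <- c("keap_roc", class(out))
  out
}

#' Area under the ROC curve
#'
#' Trapezoidal area under the empirical ROC curve; equal to the
#' Mann-Whitney concordance estimator (#concordant + 1/2 #tied) /
#' (n_pos x n_neg).
#'
#' @inheritParams roc_curve
#' @return A single number in \[0, 1\].
#' @export
roc_auc <- function(data, score, truth, direction = c("greater", "less")) {
  direction <- arg_match(direction)
  sl <- extract_scored(data, enquo(score), enquo(truth))
  check_scored_labels(sl$scores, sl$labels)
  cand <- roc_candidates(normalize_direction(sl$scores, direction), sl$labels)
  trapezoid_auc(1 - cand$specificity, cand$sensitivity)
}

#' Bootstrap confidence interval for the AUC
#'
#' Stratified percentile bootstrap: positives and negatives are resampled
#' separately (so every resample retains both classes), the AUC is
#' recomputed on each resample, and the interval is the percentile interval
#' of the bootstrap distribution.
#'
#' @inheritParams roc_curve
#' @param n_boot Number of bootstrap resamples (default 2000).
#' @param level Confidence level (default 0.95).
#' @param seed Integer seed; identical seeds give identical intervals.
#' @return One-row tibble with columns `auc`, `conf.low`, `conf.high`,
#'   `level`, `n_boot`.
#' @export
roc_auc_ci <- function(data, score, truth, direction = c("greater", "less"),
                       n_boot = 2000L, level = 0.95, seed = 1L) {
  direction <- arg_match(direction)
  if (n_boot < 1) abort("`n_boot` must be >= 1.")
  sl <- extract_scored(data, enquo(score), enquo(truth))
  check_scored_labels(sl$scores, sl$labels)
  s <- normalize_direction(sl$scores, direction)
  y <- sl$labels
  pos <- s[y]
  neg <- s[!y]
  point <- rank_auc(s, y)
  aucs <- withr::with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      bs <- c(sample(pos, length(pos), replace = TRUE),
              sample(neg, length(neg), replace = TRUE))
      by <- c(rep(TRUE, length(pos)), rep(FALSE, length(neg)))
      rank_auc(bs, by)
    }, numeric(1))
  })
  qs <- quantile(aucs, c((1 - level) / 2, 1 - (1 - level) / 2), names = FALSE)
  tibble(auc = point, conf.low = qs[1], conf.high = qs[2],
         level = level, n_boot = as.integer(n_boot))
}

# shared constructor for optimizer results
new_cutpoint_fit <- function(cutpoint, direction, sensitivity, specificity,
                             objective, min_specificity = NA_real_,
                             n_pos, n_neg, auc) {
  structure(
    list(
      cutpoint = cutpoint,
      direction = direction,
      sensitivity = sensitivity,
      specificity = specificity,
      youden_j = sensitivity + specificity - 1,
      objective = objective,
      min_specificity = min_specificity,
      n_pos = n_pos,
      n_neg = n_neg,
      auc = auc
    ),
    class = "cutpoint_fit"
  )
}

#' Youden-optimal cutpoint
#'
#' Selects, over the full candidate set (midpoints plus sentinels), the
#' cutpoint maximizing Youden's J = sensitivity + specificity - 1, the
#' training objective for all single-assay tests. Ties are broken in favor
#' of the higher sensitivity, then the smaller cutpoint. If the training
#' AUC is below 0.5 the chosen `direction` contradicts the data and a
#' `keapscreen_direction_mismatch` warning is raised.
#'
#' @inheritParams roc_curve
#' @return A `cutpoint_fit` object; see [tidy.cutpoint_fit()].
#' @export
cut_youden <- function(data, score, truth, direction = c("greater", "less")) {
  direction <- arg_match(direction)
  sl <- extract_scored(data, enquo(score), enquo(truth))
  check_scored_labels(sl$scores, sl$labels)
  s <- normalize_direction(sl$scores, direction)
  cand <- roc_candidates(s, sl$labels)
  cand$cut_orig <- denormalize_cutpoint(cand$cutpoint, direction)
  j <- cand$sensitivity + cand$specificity - 1
  best <- which(j >= max(j) - 1e-12)
  best <- best[order(-cand$sensitivity[best], cand$cut_orig[best])][1]
  auc <- trapezoid_auc(1 - cand$specificity, cand$sensitivity)
  if (auc < 0.5) {
    warn(paste0("Training AUC ", format(round(auc, 3)),
                " < 0.5: the score direction appears mismatched ",
                "to the positive class."),
         class = "keapscreen_direction_mismatch")
  }
  new_cutpoint_fit(
    cutpoint = cand$cut_orig[best], direction = direction,
    sensitivity = cand$sensitivity[best], specificity = cand$specificity[best],
    objective = "youden", n_pos = sum(sl$labels), n_neg = sum(!sl$labels),
    auc = auc
  )
}

#' Screening cutpoint: maximal sensitivity under a specificity floor
#'
#' Training objective for the first stage of the two-stage test: among
#' candidate cutpoints whose training specificity is at least
#' `min_specificity`, pick the one maximizing sensitivity; among
#' equal-sensitivity candidates, the one with the highest specificity, then
#' the smaller cutpoint. Candidates that call no sample positive are never
#' feasible -- a screen that forwards nobody to validation is vacuous -- so
#' degenerate inputs (e.g. all scores identical with a positive floor)
#' raise an infeasibility error naming the best achievable specificity.
#' The constraint is evaluated on the training data only; validation
#' specificity is simply reported downstream.
#'
#' @inheritParams roc_curve
#' @param min_specificity Specificity floor in \[0, 1); default 0.3.
#' @return A `cutpoint_fit` object with `objective = "screen_sens_at_min_spec"`
#'   and the constraint recorded in `min_specificity`.
#' @export
cut_screening <- function(data, score, truth,
                          direction = c("greater", "less"),
                          min_specificity = 0.3) {
  direction <- arg_match(direction)
  if (!is.numeric(min_specificity) || length(min_specificity) != 1 ||
      min_specificity < 0 || min_specificity >= 1) {
    abort("`min_specificity` must be a single number in [0, 1).")
  }
  sl <- extract_scored(data, enquo(score), enquo(truth))
  check_scored_labels(sl$scores, sl$labels)
  s <- normalize_direction(sl$scores, direction)
  cand <- roc_candidates(s, sl$labels)
  cand$cut_orig <- denormalize_cutpoint(cand$cutpoint, direction)
  usable <- cand$sensitivity > 0
  feasible <- usable & cand$specificity >= min_specificity
  if (!any(feasible)) {
    best_spec <- if (any(usable)) max(cand$specificity[usable]) else NA_real_
    abort(paste0(
      "No feasible screening cutpoint: best achievable specificity at ",
      "nonzero sensitivity is ", format(round(best_spec, 4)),
      " < minimum ", format(min_specificity), "."),
      class = "keapscreen_infeasible")
  }
  idx <- which(feasible)
  idx <- idx[order(-cand$sensitivity[idx], -cand$specificity[idx],
                   cand$cut_orig[idx])][1]
  new_cutpoint_fit(
    cutpoint = cand$cut_orig[idx], direction = direction,
    sensitivity = cand$sensitivity[idx], specificity = cand$specificity[idx],
    objective = "screen_sens_at_min_spec", min_specificity = min_specificity,
    n_pos = sum(sl$labels), n_neg = sum(!sl$labels),
    auc = trapezoid_auc(1 - cand$specificity, cand$sensitivity)
  )
}

#' Apply a trained cutpoint to new scores
#'
#' Deployment of a trained rule (on the validation cohort, or anywhere
#' else): a score is called positive iff `score >= cutpoint` (direction
#' `"greater"`) or `score <= cutpoint` (direction `"less"`). The `-Inf` /
#' `+Inf` sentinels therefore give all-positive / all-negative rules.
#'
#' @param scores Numeric vector of finite marker values.
#' @param rule A `cutpoint_fit` or [test_rule()] (anything with `cutpoint`
#'   and `direction` elements).
#' @return Logical vector of binary calls.
#' @export
apply_cutpoint <- function(scores, rule) {
  if (any(!is.finite(scores))) {
    abort("Scores must be finite; drop missing values before calling.")
  }
  if (is.null(rule$cutpoint) || is.null(rule$direction)) {
    abort("`rule` must carry `cutpoint` and `direction`.")
  }
  if (rule$direction == "greater") scores >= rule$cutpoint
  else scores <= rule$cutpoint
}

#' @export
print.cutpoint_fit <- function(x, ...) {
  cat("Cutpoint fit (", x$objective, ")\n", sep = "")
  cat("  cutpoint:   ", format(x$cutpoint), " (direction ", x$direction,
      ")\n", sep = "")
  cat(sprintf("  sensitivity: %.3f  specificity: %.3f  Youden J: %.3f\n",
              x$sensitivity, x$specificity, x$youden_j))
  if (!is.na(x$min_specificity)) {
    cat("  constraint:  training specificity >=", x$min_specificity, "\n")
  }
  cat(sprintf("  training data: %d positive / %d negative, AUC %.3f\n",
              x$n_pos, x$n_neg, x$auc))
  invisible(x)
}
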