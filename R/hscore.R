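#' H-score of a stain-intensity profile
#'
#' Semi-quantitative immunohistochemistry score: each tumor cell is graded
#' absent (0), mild (1+), moderate (2+) or strong (3+), and the H-score is
#' the intensity-weighted sum of the cell percentages,
#' `round(sum(intensity * percent))`, giving an integer in \[0, 300\]
#' (100 x mean intensity).
#'
#' @param profile Stain profile: percentages of cells at intensities
#'   0, 1, 2, 3. Either a numeric vector of length 4 (in intensity order,
#'   names ignored) for a single sample, or a data frame / matrix with four
#'   columns (one row per sample). Each profile must sum to 100 (tolerance
#'   1e-9 relative to 100 for fractional entries).
#' @return Integer vector of H-scores, one per profile.
#' @export
#' @examples
#' h_score(c(0, 0, 0, 100))            # 300
#' h_score(c(10, 20, 30, 40))          # 200
h_score <- function(profile) {
  m <- as_profile_matrix(profile)
  bad <- which(abs(rowSums(m) - 100) > 1e-7 | apply(m < 0, 1, any))
  if (length(bad) > 0) {
    abort(sprintf(
      "Stain profile %d: percentages must be non-negative and sum to 100 (got %s).",
      bad[1], format(sum(m[bad[1], ]))))
  }
  as.integer(round(m %*% c(0, 1, 2, 3)))
}

as_profile_matrix <- function(profile) {
  if (is.data.frame(profile)) profile <- as.matrix(profile)
  if (is.null(dim(profile))) {
    if (length(profile) != 4) {
      abort("A stain profile has exactly 4 entries (intensities 0..3).")
    }
    profile <- matrix(profile, nrow = 1)
  }
  if (ncol(profile) != 4) {
    abort("Stain profiles need 4 columns (intensities 0..3).")
  }
  if (!is.numeric(profile) || any(!is.finite(profile))) {
    abort("Stain profile percentages must be finite numbers.")
  }
  profile
}

#' Discretize a latent protein signal into a stain profile
#'
#' Models the heterogeneous per-cell staining of a sample: the cell
#' population's latent signal is normal with mean `latent` and standard
#' deviation `dispersion`, and the four intensity bins are the probability
#' masses between three ascending thresholds. Mass exactly at a boundary
#' belongs to the higher intensity bin (a fixed convention; measure zero
#' for positive dispersion). Supports the cohort simulator's H-score
#' channel.
#'
#' @param latent Numeric vector of per-sample latent protein signals.
#' @param thresholds Three strictly ascending cut values separating
#'   intensities 0|1, 1|2, 2|3.
#' @param dispersion Standard deviation of the per-cell spread; > 0.
#' @return Tibble with columns `pct_0`..`pct_3` (percentages summing to
#'   100), one row per element of `latent`.
#' @export
discretize_latent <- function(latent, thresholds, dispersion) {
  if (length(thresholds) != 3 || any(diff(thresholds) <= 0)) {
    abort("`thresholds` must be 3 strictly ascending values.")
  }
  if (!is.numeric(dispersion) || length(dispersion) != 1 || dispersion <= 0) {
    abort("`dispersion` must be a single positive number.")
  }
  # P(cell >= t_k): boundary mass goes to the higher bin, consistent with
  # the >= call convention used throughout
  upper <- vapply(thresholds,
                  function(t) pnorm(t, mean = latent, sd = dispersion,
                                    lower.tail = FALSE),
                  numeric(length(latent)))
  if (is.null(dim(upper))) upper <- matrix(upper, nrow = 1)
  p3 <- upper[, 3]
  p2 <- upper[, 2] - upper[, 3]
  p1 <- upper[, 1] - upper[, 2]
  p0 <- 1 - upper[, 1]
  tibble(pct_0 = 100 * p0, pct_1 = 100 * p1,
         pct_2 = 100 * p2, pct_3 = 100 * p3)
}
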