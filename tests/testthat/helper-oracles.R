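# Independent brute-force oracles, deliberately naive: pairwise AUC
# counting and exhaustive cutpoint search over explicitly enumerated
# candidates. These never share code with the package's engine.

oracle_auc <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  total <- 0
  for (p in pos) {
    for (q in neg) {
      total <- total + (p > q) + 0.5 * (p == q)
    }
  }
  total / (length(pos) * length(neg))
}

oracle_candidates <- function(scores) {
  d <- sort(unique(scores))
  mids <- if (length(d) > 1) (d[-1] + d[-length(d)]) / 2 else numeric(0)
  c(-Inf, mids, Inf)
}

oracle_confusion <- function(scores, labels, cutpoint, direction) {
  calls <- if (direction == "greater") scores >= cutpoint else scores <= cutpoint
  list(
    sens = sum(calls & labels) / sum(labels),
    spec = sum(!calls & !labels) / sum(!labels)
  )
}

oracle_youden <- function(scores, labels, direction = "greater") {
  cands <- oracle_candidates(scores)
  best <- NULL
  for (ct in cands) {
    cf <- oracle_confusion(scores, labels, ct, direction)
    j <- cf$sens + cf$spec - 1
    if (is.null(best) || j > best$j + 1e-12 ||
        (abs(j - best$j) <= 1e-12 &&
         (cf$sens > best$sens + 1e-12 ||
          (abs(cf$sens - best$sens) <= 1e-12 && ct < best$cutpoint)))) {
      best <- list(cutpoint = ct, j = j, sens = cf$sens, spec = cf$spec)
    }
  }
  best
}

oracle_screening <- function(scores, labels, direction = "greater",
                             min_spec = 0.3) {
  cands <- oracle_candidates(scores)
  best <- NULL
  for (ct in cands) {
    cf <- oracle_confusion(scores, labels, ct, direction)
    if (cf$sens <= 0 || cf$spec < min_spec) next
    if (is.null(best) || cf$sens > best$sens + 1e-12 ||
        (abs(cf$sens - best$sens) <= 1e-12 &&
         (cf$spec > best$spec + 1e-12 ||
          (abs(cf$spec - best$spec) <= 1e-12 && ct < best$cutpoint)))) {
      best <- list(cutpoint = ct, sens = cf$sens, spec = cf$spec)
    }
  }
  best
}

# random small scored-label instance with ties (integer score grid)
random_instance <- function() {
  n <- sample(4:50, 1)
  scores <- sample(0:8, n, replace = TRUE) +
    sample(c(0, 0.5), n, replace = TRUE)
  labels <- sample(c(TRUE, FALSE), n, replace = TRUE)
  # guarantee both classes
  labels[sample(n, 1)] <- TRUE
  labels[which(labels)[1]] <- TRUE
  if (all(labels)) labels[sample(n, 1)] <- FALSE
  if (sum(!labels) == 0) labels[1] <- FALSE
  if (sum(labels) == 0) labels[1] <- TRUE
  tibble::tibble(score = scores, label = labels)
}

# small hand-assembled cohort for IO / evaluation tests
tiny_cohort <- function() {
  tibble::tibble(
    sample_id = c("a", "b", "c"),
    histology = c("LUAD", "LUAD", "LUSC"),
    mutation_status = c("KEAP1mut", "WT", "NFE2L2mut"),
    h_score = c(210L, NA_integer_, 90L),
    k1n2_score = c(2.5, -0.3, 1.9),
    k1n2_call = c(TRUE, FALSE, TRUE),
    NQO1 = c(8.1, 5.9, 7.7),
    TXNRD1 = c(9.0, 6.2, 8.4)
  )
}
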