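test_that("youden_j computes the index and rejects out-of-range input", {
  expect_equal(youden_j(0.87, 0.87), 0.74)
  expect_equal(youden_j(1, 1), 1)
  expect_equal(youden_j(0.5, 0.5), 0)
  expect_error(youden_j(1.2, 0.5), "proportions")
  expect_error(youden_j(0.5, -0.1), "proportions")
})

test_that("evaluate_test counts match an independent per-sample recount", {
  co <- simulate_cohort(sim_params("paper_like", n_samples = 30, seed = 41))
  rule <- test_rule("TXNRD1", 7)
  rep <- evaluate_test(co, rule, reference = "mutation_status")
  calls <- co$TXNRD1 >= 7
  lab <- is_mutant(co$mutation_status)
  expect_equal(rep$tp, sum(calls & lab))
  expect_equal(rep$fp, sum(calls & !lab))
  expect_equal(rep$tn, sum(!calls & !lab))
  expect_equal(rep$fn, sum(!calls & lab))
  expect_equal(rep$tp + rep$fp + rep$tn + rep$fn, rep$n_evaluated)
  expect_equal(rep$sensitivity, rep$tp / (rep$tp + rep$fn))
  expect_equal(rep$specificity, rep$tn / (rep$tn + rep$fp))
  expect_equal(rep$youden_j, rep$sensitivity + rep$specificity - 1)
})

test_that("all-positive and separable rules hit the metric boundaries", {
  co <- simulate_cohort(sim_params("paper_like", n_samples = 60, seed = 43))
  rep <- evaluate_test(co, test_rule("TXNRD1", -Inf))
  expect_equal(rep$sensitivity, 1)
  expect_equal(rep$specificity, 0)
  expect_equal(rep$youden_j, 0)
  sep <- simulate_cohort(sim_params("separable", n_samples = 60, seed = 43))
  rep2 <- evaluate_test(sep, test_rule("TXNRD1", 6 + 6)) # true midpoint
  expect_equal(rep2$youden_j, 1)
})

test_that("samples missing the marker or label are dropped and counted", {
  co <- simulate_cohort(sim_params("paper_like", n_samples = 40, seed = 45))
  co$h_score[1:10] <- NA_integer_
  rep <- evaluate_test(co, test_rule("h_score", 100))
  expect_equal(rep$n_dropped_missing, 10L)
  expect_equal(rep$n_evaluated, 30L)
  one_class <- co[is_mutant(co$mutation_status), ]
  expect_error(evaluate_test(one_class, test_rule("h_score", 100)),
               "no negative")
})

test_that("combined evaluation short-circuits per the two-stage algorithm", {
  co <- simulate_cohort(sim_params("paper_like", n_samples = 120, seed = 47))
  validator <- k1n2_rule()
  # all-positive screen: final report identical to the validator alone
  all_pos <- combined_rule(test_rule("TXNRD1", -Inf), validator)
  both <- evaluate_combined(co, all_pos)
  val_alone <- evaluate_test(co, validator)
  final <- both[both$stage == "combined", ]
  expect_equal(final$tp, val_alone$tp)
  expect_equal(final$fp, val_alone$fp)
  expect_equal(final$youden_j, val_alone$youden_j)
  # all-negative screen: no positives at all
  all_neg <- combined_rule(test_rule("TXNRD1", Inf), validator)
  final2 <- evaluate_combined(co, all_neg)
  final2 <- final2[final2$stage == "combined", ]
  expect_equal(final2$sensitivity, 0)
  expect_equal(final2$specificity, 1)
  expect_equal(final2$n_validated, 0L)
})

test_that("final positives are exactly the intersection of the two tests", {
  co <- simulate_cohort(sim_params("paper_like", n_samples = 200, seed = 49))
  screen <- test_rule("NQO1", 7)
  validator <- k1n2_rule()
  rep <- evaluate_combined(co, combined_rule(screen, validator))
  final <- rep[rep$stage == "combined", ]
  s_pos <- apply_cutpoint(co$NQO1, screen)
  v_pos <- as.numeric(co$k1n2_call) >= 0.5
  expect_equal(final$tp + final$fp, sum(s_pos & v_pos))
  expect_equal(rep$n_validated[1], sum(s_pos))
})

test_that("k1n2_reduction is the screen-negative fraction and complements forwarding", {
  co <- simulate_cohort(sim_params("paper_like", n_samples = 10, seed = 51))
  expect_equal(k1n2_reduction(co, test_rule("TXNRD1", -Inf)), 0)
  expect_equal(k1n2_reduction(co, test_rule("TXNRD1", Inf)), 1)
  cut <- sort(co$TXNRD1)[4] # exactly 3 samples below
  red <- k1n2_reduction(co, test_rule("TXNRD1", cut))
  expect_equal(red, 0.3)
  forwarded <- mean(apply_cutpoint(co$TXNRD1, test_rule("TXNRD1", cut)))
  expect_identical(red + forwarded, 1)
})

test_that("train_test_suite emits the marker x stratum x objective cross product", {
  co <- split_cohort(
    simulate_cohort(sim_params("paper_like", n_samples = 300, seed = 53)),
    seed = 1)
  suite <- train_test_suite(co, markers = c("TXNRD1", "NQO1"))
  expect_equal(sum(suite$type == "single"), 12L) # 2 markers x 3 strata x 2 objectives
  expect_equal(sum(suite$type == "combined"), 6L) # screening objective only
  expect_equal(sum(suite$type == "validator"), 3L) # one passthrough per stratum
  expect_true(all(suite$status == "ok"))
  # screening rows respect the floor on training data
  scr <- suite[suite$objective == "screening" & suite$type == "single", ]
  expect_true(all(scr$train_specificity >= 0.3))
})

test_that("training failures are isolated per stratum", {
  co <- simulate_cohort(sim_params("paper_like", n_samples = 300, seed = 55))
  co$mutation_status[co$histology == "LUSC"] <- "WT" # no LUSC positives
  co <- split_cohort(co, strata = "histology", seed = 1)
  suite <- train_test_suite(co, markers = "TXNRD1")
  lusc <- suite[suite$stratum == "LUSC" & suite$type == "single", ]
  expect_true(all(lusc$status == "error"))
  expect_match(lusc$message[1], "positive")
  other <- suite[suite$stratum != "LUSC" & suite$type == "single", ]
  expect_true(all(other$status == "ok"))
})

test_that("on separable cohorts every trained rule attains validation J = 1", {
  co <- split_cohort(
    simulate_cohort(sim_params("separable", n_samples = 600, seed = 57)),
    seed = 2)
  suite <- train_test_suite(co, markers = c(cohort_panel(co), "h_score"))
  rep <- evaluate_suite(co, suite)
  final <- rep[rep$status == "ok" & rep$stage != "screen", ]
  expect_gt(nrow(final), 30)
  expect_true(all(final$youden_j == 1))
})

test_that("training never reads validation labels", {
  co <- split_cohort(
    simulate_cohort(sim_params("paper_like", n_samples = 300, seed = 59)),
    seed = 3)
  suite1 <- train_test_suite(co, markers = c("TXNRD1", "h_score"))
  perm <- co
  vi <- which(perm$split_group == "validation")
  withr::with_seed(1, perm$mutation_status[vi] <-
                     sample(perm$mutation_status[vi]))
  suite2 <- train_test_suite(perm, markers = c("TXNRD1", "h_score"))
  expect_identical(suite1$cutpoint, suite2$cutpoint)
  expect_identical(suite1$train_j, suite2$train_j)
})

test_that("the paper-like qualitative ordering holds: combined >= validator >= IHC", {
  # pooled stratum, mutation reference: the screen filters part of the
  # validator's idiosyncratic false positives, so the two-stage test beats
  # the validator alone, which beats the noisy attenuated IHC single test
  ok <- vapply(1:25, function(i) {
    co <- split_cohort(
      simulate_cohort(sim_params("paper_like", n_samples = 5000, seed = i)),
      seed = i)
    use <- subset_cohort(co, split_group = "use")
    val <- subset_cohort(co, split_group = "validation")
    use$..lab <- reference_label(use, "mutation_status")
    screen <- as_test_rule(
      cut_screening(use, TXNRD1, ..lab, min_specificity = 0.3), "TXNRD1")
    comb <- evaluate_combined(val, combined_rule(screen, k1n2_rule()))
    j_comb <- comb$youden_j[comb$stage == "combined"]
    j_val <- evaluate_test(val, k1n2_rule())$youden_j
    ihc <- as_test_rule(suppressWarnings(cut_youden(use, h_score, ..lab)),
                        "h_score")
    j_ihc <- evaluate_test(val, ihc)$youden_j
    j_comb >= j_val && j_val >= j_ihc
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})

test_that("rule tidiers report marker, cutpoint and stages", {
  r <- test_rule("NQO1", 7.5)
  expect_equal(tidy(r)$marker, "NQO1")
  cr <- combined_rule(r, k1n2_rule())
  td <- tidy(cr)
  expect_equal(td$stage, c("screen", "validate"))
  expect_equal(td$marker, c("NQO1", "k1n2_call"))
})
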