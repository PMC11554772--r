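test_that("roc_curve has fixed endpoints and monotone staircase", {
  d <- tibble::tibble(x = c(3, 5, 1, 4), y = c(TRUE, TRUE, FALSE, FALSE))
  rc <- roc_curve(d, x, y)
  expect_equal(rc$fpr[1], 0)
  expect_equal(rc$tpr[1], 0)
  expect_equal(rc$fpr[nrow(rc)], 1)
  expect_equal(rc$tpr[nrow(rc)], 1)
  expect_true(all(diff(rc$fpr) >= 0))
  expect_true(all(diff(rc$tpr) >= 0))
  expect_equal(attr(rc, "auc"), 0.75)
})

test_that("perfectly separated scores pass through (0,1) with AUC 1", {
  d <- tibble::tibble(x = c(10, 11, 1, 2), y = c(TRUE, TRUE, FALSE, FALSE))
  rc <- roc_curve(d, x, y)
  expect_true(any(rc$fpr == 0 & rc$tpr == 1))
  expect_equal(roc_auc(d, x, y), 1)
})

test_that("all-tied scores give the degenerate two-point curve and AUC 0.5", {
  d <- tibble::tibble(x = rep(2, 6), y = rep(c(TRUE, FALSE), 3))
  rc <- roc_curve(d, x, y)
  expect_equal(nrow(rc), 2L)
  expect_equal(roc_auc(d, x, y), 0.5)
})

test_that("single-class input signals an undefined ROC", {
  d <- tibble::tibble(x = 1:4, y = rep(TRUE, 4))
  expect_error(roc_auc(d, x, y), "positive and.*negative|ROC undefined")
  expect_error(roc_curve(d, x, y), "positive and.*negative|ROC undefined")
})

test_that("trapezoidal AUC equals pairwise concordance counting on random data", {
  withr::with_seed(42, {
    for (i in 1:200) {
      inst <- random_instance()
      expect_equal(roc_auc(inst, score, label),
                   oracle_auc(inst$score, inst$label), tolerance = 1e-12)
    }
  })
})

test_that("trapezoidal AUC agrees with pROC on random tied data", {
  withr::with_seed(7, {
    for (i in 1:20) {
      inst <- random_instance()
      ref <- as.numeric(pROC::auc(pROC::roc(
        response = inst$label, predictor = inst$score,
        direction = "<", quiet = TRUE)))
      expect_equal(roc_auc(inst, score, label), ref, tolerance = 1e-12)
    }
  })
})

test_that("cut_youden reproduces hand-worked optima and the tie-break", {
  d <- tibble::tibble(x = c(10, 11, 1, 2), y = c(TRUE, TRUE, FALSE, FALSE))
  f <- cut_youden(d, x, y)
  expect_equal(f$cutpoint, 6)
  expect_equal(f$youden_j, 1)
  # two maximizers with J = 2/3; sensitivity-favoring tie-break picks 1.5
  d2 <- tibble::tibble(x = c(2, 3, 4, 0, 1, 2),
                       y = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  f2 <- cut_youden(d2, x, y)
  expect_equal(f2$cutpoint, 1.5)
  expect_equal(f2$youden_j, 2 / 3, tolerance = 1e-12)
  expect_equal(f2$sensitivity, 1)
})

test_that("inverted labels hit the boundary sentinel with a direction warning", {
  d <- tibble::tibble(x = c(10, 11, 1, 2), y = c(FALSE, FALSE, TRUE, TRUE))
  expect_warning(f <- cut_youden(d, x, y),
                 class = "keapscreen_direction_mismatch")
  expect_equal(f$youden_j, 0)
  expect_true(is.infinite(f$cutpoint))
})

test_that("cut_screening maximizes sensitivity under the specificity floor", {
  d <- tibble::tibble(x = c(1:5, 0:4), y = rep(c(TRUE, FALSE), each = 5))
  f <- cut_screening(d, x, y, min_specificity = 0.3)
  expect_equal(f$cutpoint, 1.5)
  expect_equal(f$sensitivity, 0.8)
  expect_equal(f$specificity, 0.4)
  expect_equal(f$min_specificity, 0.3)
  # perfectly separated data: sens and spec 1 regardless of the floor
  d2 <- tibble::tibble(x = c(5, 6, 1, 2), y = c(TRUE, TRUE, FALSE, FALSE))
  f2 <- cut_screening(d2, x, y, min_specificity = 0.3)
  expect_equal(f2$sensitivity, 1)
  expect_equal(f2$specificity, 1)
  # vacuous floor: the most specific among the sensitivity-1 candidates
  d3 <- tibble::tibble(x = c(1, 2, 0, 1), y = c(TRUE, TRUE, FALSE, FALSE))
  f3 <- cut_screening(d3, x, y, min_specificity = 0)
  expect_equal(f3$sensitivity, 1)
  expect_equal(f3$specificity, 0.5)
})

test_that("an unreachable specificity floor raises the infeasibility error", {
  d <- tibble::tibble(x = rep(3, 8), y = rep(c(TRUE, FALSE), 4))
  expect_error(cut_screening(d, x, y, min_specificity = 0.3),
               class = "keapscreen_infeasible")
  expect_error(cut_screening(d, x, y, min_specificity = 0.3),
               "best achievable specificity")
})

test_that("both optimizers match exhaustive brute-force search on random data", {
  withr::with_seed(101, {
    for (i in 1:200) {
      inst <- random_instance()
      fy <- suppressWarnings(cut_youden(inst, score, label))
      oy <- oracle_youden(inst$score, inst$label)
      expect_equal(fy$youden_j, oy$j, tolerance = 1e-12)
      expect_equal(fy$cutpoint, oy$cutpoint)
      os <- oracle_screening(inst$score, inst$label, min_spec = 0.3)
      if (is.null(os)) {
        expect_error(cut_screening(inst, score, label, min_specificity = 0.3),
                     class = "keapscreen_infeasible")
      } else {
        fs <- cut_screening(inst, score, label, min_specificity = 0.3)
        expect_equal(fs$sensitivity, os$sens, tolerance = 1e-12)
        expect_equal(fs$specificity, os$spec, tolerance = 1e-12)
        expect_equal(fs$cutpoint, os$cutpoint)
      }
    }
  })
})

test_that("AUC and optimizer operating points are invariant to monotone transforms", {
  withr::with_seed(11, {
    for (i in 1:50) {
      inst <- random_instance()
      tr <- dplyr::mutate(inst, score = exp(score / 3) - 2)
      expect_equal(roc_auc(inst, score, label), roc_auc(tr, score, label),
                   tolerance = 1e-12)
      a <- suppressWarnings(cut_youden(inst, score, label))
      b <- suppressWarnings(cut_youden(tr, score, label))
      expect_equal(a$sensitivity, b$sensitivity)
      expect_equal(a$specificity, b$specificity)
      expect_equal(a$youden_j, b$youden_j, tolerance = 1e-12)
    }
  })
})

test_that("direction 'less' mirrors direction 'greater' on negated scores", {
  withr::with_seed(23, {
    for (i in 1:25) {
      inst <- random_instance()
      neg <- dplyr::mutate(inst, score = -score)
      expect_equal(roc_auc(inst, score, label),
                   roc_auc(neg, score, label, direction = "less"),
                   tolerance = 1e-12)
      a <- suppressWarnings(cut_youden(inst, score, label))
      b <- suppressWarnings(cut_youden(neg, score, label,
                                       direction = "less"))
      expect_equal(a$youden_j, b$youden_j, tolerance = 1e-12)
      expect_equal(b$cutpoint, -a$cutpoint)
    }
  })
})

test_that("apply_cutpoint uses the >= boundary convention and sentinels", {
  r <- test_rule("x", 1.5)
  expect_identical(apply_cutpoint(c(1.4, 1.5, 1.6), r),
                   c(FALSE, TRUE, TRUE))
  expect_true(all(apply_cutpoint(c(-5, 0, 5), test_rule("x", -Inf))))
  expect_false(any(apply_cutpoint(c(-5, 0, 5), test_rule("x", Inf))))
  rl <- test_rule("x", 1.5, direction = "less")
  expect_identical(apply_cutpoint(c(1.4, 1.5, 1.6), rl),
                   c(TRUE, TRUE, FALSE))
})

test_that("bootstrap interval is degenerate at perfect separation and seeded", {
  d <- tibble::tibble(x = c(10, 11, 12, 1, 2, 3),
                      y = rep(c(TRUE, FALSE), each = 3))
  ci <- roc_auc_ci(d, x, y, n_boot = 200, seed = 5)
  expect_equal(ci$conf.low, 1)
  expect_equal(ci$conf.high, 1)
  ci2 <- roc_auc_ci(d, x, y, n_boot = 200, seed = 5)
  expect_identical(ci, ci2)
})

test_that("bootstrap intervals stay in [0,1], cover the estimate, and shrink with n", {
  widths <- sapply(c(40, 400, 4000), function(n) {
    withr::with_seed(n, {
      d <- tibble::tibble(
        x = c(rnorm(n / 2, 1.5), rnorm(n / 2)),
        y = rep(c(TRUE, FALSE), each = n / 2)
      )
      ci <- roc_auc_ci(d, x, y, n_boot = 400, seed = 3)
      expect_gte(ci$conf.low, 0)
      expect_lte(ci$conf.high, 1)
      expect_lte(ci$conf.low, ci$auc)
      expect_gte(ci$conf.high, ci$auc)
      ci$conf.high - ci$conf.low
    })
  })
  expect_true(all(diff(widths) < 0))
})

test_that("bootstrap interval covers the point estimate across replicate datasets", {
  withr::with_seed(77, {
    covered <- vapply(1:100, function(i) {
      d <- tibble::tibble(
        x = c(rnorm(20, 1.5), rnorm(20)),
        y = rep(c(TRUE, FALSE), each = 20)
      )
      ci <- roc_auc_ci(d, x, y, n_boot = 2000, seed = i)
      ci$conf.low <= ci$auc && ci$auc <= ci$conf.high
    }, logical(1))
    expect_gte(mean(covered), 0.99)
  })
})

test_that("tidy and glance expose the cutpoint fit", {
  d <- tibble::tibble(x = c(1:5, 0:4), y = rep(c(TRUE, FALSE), each = 5))
  f <- cut_screening(d, x, y, min_specificity = 0.3)
  td <- tidy(f)
  expect_equal(td$youden_j, td$sensitivity + td$specificity - 1)
  expect_equal(td$min_specificity, 0.3)
  gl <- glance(f)
  expect_equal(gl$n_pos, 5L)
  expect_equal(gl$n_neg, 5L)
})
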