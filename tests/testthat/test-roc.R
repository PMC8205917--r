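test_that("AUC equals the exhaustive pairwise kernel mean, ties included", {
  r <- roc_delong(c(2, 3, 4, 1, 2, 3), rep(c(TRUE, FALSE), each = 3))
  expect_equal(r$auc, 7 / 9)
  set.seed(20)
  for (i in 1:20) {
    n1 <- sample(3:25, 1); n0 <- sample(3:25, 1)
    sc <- round(c(rnorm(n1, 0.5), rnorm(n0)), 1)
    y <- rep(c(TRUE, FALSE), c(n1, n0))
    r <- roc_delong(sc, y)
    expect_equal(r$auc, oracle_auc(sc[y], sc[!y]))
    # trapezoidal area under the reported curve equals the AUC
    cu <- r$curve
    trap <- sum(diff(cu$fpr) * (head(cu$tpr, -1) + tail(cu$tpr, -1)) / 2)
    expect_equal(trap, r$auc, tolerance = 1e-12)
    expect_equal(c(cu$fpr[1], cu$tpr[1]), c(0, 0))
    expect_equal(c(tail(cu$fpr, 1), tail(cu$tpr, 1)), c(1, 1))
    expect_true(all(diff(cu$fpr) >= 0) && all(diff(cu$tpr) >= 0))
  }
})

test_that("complete separation gives AUC 1 with a degenerate CI", {
  r <- roc_delong(c(10, 11, 12, 1, 2, 3), rep(c(TRUE, FALSE), each = 3))
  expect_equal(r$auc, 1)
  expect_equal(r$auc_var, 0)
  expect_equal(r$auc_ci, c(1, 1))
})

test_that("negating scores maps AUC to 1 - AUC", {
  set.seed(21)
  sc <- rnorm(40)
  y <- rep(c(TRUE, FALSE), each = 20)
  expect_equal(roc_delong(-sc, y)$auc, 1 - roc_delong(sc, y)$auc)
})

test_that("DeLong AUC variance and paired test agree with pROC", {
  skip_if_not_installed("pROC")
  set.seed(22)
  y <- rep(c(TRUE, FALSE), c(40, 40))
  a <- rnorm(80) + y * 1.2
  b <- 0.6 * a + rnorm(80) * 0.8
  r <- roc_delong(a, y)
  pr <- pROC::roc(response = y, predictor = a, quiet = TRUE, direction = "<")
  expect_equal(r$auc, as.numeric(pROC::auc(pr)))
  expect_equal(r$auc_var, as.numeric(pROC::var(pr, method = "delong")))
  dt <- delong_test(a, b, y)
  pt <- pROC::roc.test(pr, pROC::roc(response = y, predictor = b, quiet = TRUE,
                                     direction = "<"),
                       method = "delong", paired = TRUE)
  expect_equal(dt$p_value, as.numeric(pt$p.value))
})

test_that("paired test degenerates to p = 1 for identical or rank-equal scores", {
  sc <- c(3, 1, 4, 1, 5, 0)
  y <- rep(c(TRUE, FALSE), each = 3)
  expect_equal(delong_test(sc, sc, y)$p_value, 1)
  expect_equal(delong_test(sc, exp(sc), y)$p_value, 1)  # monotone transform
  expect_error(delong_test(sc, sc[-1], y), "equal length")
})

test_that("confusion metrics reproduce printed Wald intervals and counts", {
  # sensitivity 0.983 = 696/708 prints as CI (0.974-0.993); the interval
  # comes from the exact count, not the rounded proportion
  ci <- mirpanel:::wald_ci(696 / 708, 708)
  expect_equal(round(ci, 3), c(0.974, 0.993))
  # integer bookkeeping
  sc <- c(rep(1, 696), rep(-1, 13), rep(-1, 693), rep(1, 16))
  y <- rep(c(TRUE, FALSE), c(709, 709))
  cm <- confusion_at_cutoff(sc, y)
  expect_equal(cm$tp, 696)
  expect_equal(cm$accuracy, 1389 / 1418)
  # all correct: upper limits clipped at 1
  cm1 <- confusion_at_cutoff(c(1, 1, -1, -1), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(cm1$accuracy, 1)
  expect_equal(cm1$acc_hi, 1)
  expect_equal(cm1$sens_lo, 1)  # clipped from below impossible; p=1 -> se=0
})

test_that("accuracy chi-squared matches the hand formula and is symmetric", {
  expect_equal(compare_accuracy_chi2(90, 100, 90, 100)$p_value, 1)
  r <- compare_accuracy_chi2(90, 100, 70, 100)
  expect_equal(r$statistic, 12.5)
  expect_equal(r$p_value, pchisq(12.5, 1, lower.tail = FALSE))
  r2 <- compare_accuracy_chi2(70, 100, 90, 100)
  expect_equal(r2$statistic, r$statistic)
  expect_warning(z <- compare_accuracy_chi2(100, 100, 100, 100), "degenerate")
  expect_equal(z$p_value, 1)
})

test_that("predictive values follow the Bayes identities", {
  expect_equal(unlist(predictive_values(1, 1, 0.3)), c(ppv = 1, npv = 1))
  expect_equal(predictive_values(0.8, 0.9, 0.5)$ppv, 8 / 9)
  # uninformative test: ppv = prevalence, npv = 1 - prevalence
  r <- predictive_values(0.7, 0.3, 0.2)
  expect_equal(r$ppv, 0.2)
  expect_equal(r$npv, 0.8)
  expect_warning(r0 <- predictive_values(0, 1, 0.5), "undefined")
  expect_true(is.na(r0$ppv))
})

test_that("baseline balance tests: identical tables give p = 1 everywhere", {
  ch <- quick_cohort(n = 40, n_mirna = 10, seed = 30)
  res <- baseline_balance_tests(ch$samples, ch$samples)
  expect_true(all(res$p_value == 1))
  expect_setequal(res$covariate,
                  c("age", "gender", "control_source", "stage", "histology"))
})

test_that("equal stage proportions across arms give chi-squared p = 1", {
  mk <- function(n, prefix) sample_table(tibble::tibble(
    sample_id = sprintf("%s%04d", prefix, 1:n),
    group = "case", control_source = "none", age = 65, gender = "male",
    stage = rep(c("IA", "IB", "II"), round(n * c(0.952, 0.041, 0.007)))[1:n],
    histology = "differentiated"))
  a <- mk(1000, "A"); b <- mk(1000, "B")
  # constant gender/histology and all-none control_source are skipped with warnings
  row <- suppressWarnings(baseline_balance_tests(a, b))
  expect_equal(row$p_value[row$covariate == "stage"], 1)
})

test_that("arms drawn from one configuration look balanced", {
  rejections <- 0L; total <- 0L
  for (seed in 1:5) {
    a <- quick_cohort(n = 100, n_mirna = 10, seed = seed)$samples
    b <- quick_cohort(n = 100, n_mirna = 10, seed = seed + 100)$samples
    res <- baseline_balance_tests(a, b)
    rejections <- rejections + sum(res$p_value < 0.05)
    total <- total + nrow(res)
  }
  expect_lte(rejections, 5L)   # ~alpha * 25 covariate-seed combinations
})
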