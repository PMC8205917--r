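wald_ci <- function(p, n, clip = c(0, 1)) {
  half <- 1.96 * sqrt(p * (1 - p) / n)
  pmin(pmax(c(p - half, p + half), clip[1]), clip[2])
}

## DeLong structural components via midranks (ties handled).
## V10: one value per case; V01: one per control; mean(V10) = AUC.
delong_components <- function(scores, y) {
  x <- scores[y]; z <- scores[!y]
  n1 <- length(x); n0 <- length(z)
  if (!n1 || !n0) abort("both classes must be nonempty")
  r_all <- rank(c(x, z))
  v10 <- (r_all[seq_len(n1)] - rank(x)) / n0
  v01 <- 1 - (r_all[n1 + seq_len(n0)] - rank(z)) / n1
  list(v10 = v10, v01 = v01, auc = mean(v10))
}

safe_var <- function(x) if (length(x) < 2L) 0 else var(x)

#' ROC curve and AUC with DeLong inference
#'
#' The AUC is the mean over all case-control pairs of the Mann-Whitney
#' kernel (1 if the case scores higher, 1/2 on ties), computed through
#' midranks; its variance comes from the per-observation DeLong
#' structural components, and the 95% CI is the normal approximation
#' clipped to \[0, 1\]. The ROC curve is evaluated at every distinct
#' score (classify positive when `score >= threshold`); its trapezoidal
#' area equals the AUC.
#'
#' @param scores numeric index values.
#' @param labels logical (`TRUE` = case) or `"case"`/`"control"`.
#' @return an object of class `roc_result`: a list with `auc`,
#'   `auc_var`, `auc_ci`, the `curve` tibble (`threshold`, `fpr`,
#'   `tpr`), and the class sizes.
#' @export
roc_delong <- function(scores, labels) {
  y <- as_case_logical(labels)
  comp <- delong_components(scores, y)
  n1 <- sum(y); n0 <- sum(!y)
  v <- safe_var(comp$v10) / n1 + safe_var(comp$v01) / n0
  ci <- pmin(pmax(comp$auc + c(-1.96, 1.96) * sqrt(v), 0), 1)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  curve <- tibble::tibble(
    threshold = thr,
    fpr = vapply(thr, function(t) mean(scores[!y] >= t), numeric(1)),
    tpr = vapply(thr, function(t) mean(scores[y] >= t), numeric(1)))
  structure(list(auc = comp$auc, auc_var = v, auc_ci = ci, curve = curve,
                 n_case = n1, n_control = n0),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC: AUC %.4f (95%% CI %.4f-%.4f), %d cases / %d controls\n",
              x$auc, x$auc_ci[1], x$auc_ci[2], x$n_case, x$n_control))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.roc_result <- function(x, ...) x$curve

#' @exportS3Method generics::glance
glance.roc_result <- function(x, ...) {
  tibble::tibble(auc = x$auc, auc_lo = x$auc_ci[1], auc_hi = x$auc_ci[2],
                 n_case = x$n_case, n_control = x$n_control)
}

#' Paired DeLong test for two correlated AUCs
#'
#' Compares the AUCs of two score vectors over the same samples using
#' the covariance of their DeLong structural components;
#' `z = (auc_a - auc_b) / se` with a two-sided normal p-value. If the
#' variance of the difference degenerates to zero with equal AUCs the
#' p-value is 1.
#'
#' @param scores_a,scores_b score vectors over the same samples.
#' @param labels logical (`TRUE` = case) or `"case"`/`"control"`.
#' @return a one-row tibble: `auc_a`, `auc_b`, `z`, `p_value`.
#' @export
delong_test <- function(scores_a, scores_b, labels) {
  if (length(scores_a) != length(scores_b)) abort("score vectors must have equal length")
  y <- as_case_logical(labels)
  ca <- delong_components(scores_a, y)
  cb <- delong_components(scores_b, y)
  v <- safe_var(ca$v10 - cb$v10) / sum(y) + safe_var(ca$v01 - cb$v01) / sum(!y)
  d <- ca$auc - cb$auc
  if (v <= 0) {
    z <- if (d == 0) 0 else sign(d) * Inf
  } else {
    z <- d / sqrt(v)
  }
  tibble::tibble(auc_a = ca$auc, auc_b = cb$auc, z = z,
                 p_value = 2 * pnorm(-abs(z)))
}

#' Confusion-matrix metrics at a cutoff
#'
#' Classifies positive when `score >= cutoff` and reports counts,
#' sensitivity, specificity and accuracy with Wald 95% CIs clipped to
#' \[0, 1\].
#'
#' @param scores numeric index values.
#' @param labels logical (`TRUE` = case) or `"case"`/`"control"`.
#' @param cutoff classification threshold (default 0).
#' @return a one-row tibble.
#' @export
confusion_at_cutoff <- function(scores, labels, cutoff = 0) {
  y <- as_case_logical(labels)
  if (!sum(y) || !sum(!y)) abort("both classes must be nonempty")
  pos <- scores >= cutoff
  tp <- sum(pos & y); fn <- sum(!pos & y)
  tn <- sum(!pos & !y); fp <- sum(pos & !y)
  sens <- tp / (tp + fn); spec <- tn / (tn + fp)
  acc <- (tp + tn) / length(y)
  s_ci <- wald_ci(sens, tp + fn); p_ci <- wald_ci(spec, tn + fp)
  a_ci <- wald_ci(acc, length(y))
  tibble::tibble(tp = tp, fp = fp, tn = tn, fn = fn,
                 sensitivity = sens, sens_lo = s_ci[1], sens_hi = s_ci[2],
                 specificity = spec, spec_lo = p_ci[1], spec_hi = p_ci[2],
                 accuracy = acc, acc_lo = a_ci[1], acc_hi = a_ci[2])
}

#' Pearson chi-squared comparison of two accuracies
#'
#' 1-df Pearson chi-squared (no continuity correction) on the 2x2 table
#' correct/incorrect x model.
#'
#' @param correct_a,correct_b numbers of correctly classified samples.
#' @param n_a,n_b totals.
#' @return a one-row tibble: `statistic`, `p_value`.
#' @export
compare_accuracy_chi2 <- function(correct_a, n_a, correct_b, n_b) {
  stopifnot(correct_a <= n_a, correct_b <= n_b)
  tab <- rbind(c(correct_a, n_a - correct_a), c(correct_b, n_b - correct_b))
  if (any(colSums(tab) == 0) || any(rowSums(tab) == 0)) {
    warn("degenerate margin; chi-squared undefined, p = 1")
    return(tibble::tibble(statistic = 0, p_value = 1))
  }
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat <- sum((tab - e)^2 / e)
  tibble::tibble(statistic = stat, p_value = pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Predictive values at a screening prevalence
#'
#' Bayes bookkeeping: `ppv = sens p / (sens p + (1 - spec)(1 - p))` and
#' `npv = spec (1 - p) / (spec (1 - p) + (1 - sens) p)`. An undefined
#' value (zero denominator) is returned as `NA` with a warning.
#'
#' @param sensitivity,specificity,prevalence proportions in \[0, 1\].
#' @return a one-row tibble: `ppv`, `npv`.
#' @export
predictive_values <- function(sensitivity, specificity, prevalence) {
  for (v in c(sensitivity, specificity, prevalence)) {
    assert_scalar_number(v, "sensitivity/specificity/prevalence", 0, 1)
  }
  p <- prevalence
  d_ppv <- sensitivity * p + (1 - specificity) * (1 - p)
  d_npv <- specificity * (1 - p) + (1 - sensitivity) * p
  ppv <- if (d_ppv > 0) sensitivity * p / d_ppv else NA_real_
  npv <- if (d_npv > 0) specificity * (1 - p) / d_npv else NA_real_
  if (anyNA(c(ppv, npv))) warn("predictive value undefined (zero denominator)")
  tibble::tibble(ppv = ppv, npv = npv)
}

#' Baseline covariate balance between two sample tables
#'
#' Age is compared with a pooled-variance two-sample t-test; gender,
#' stage, histology and control source with Pearson chi-squared tests
#' (no continuity correction). `"none"` placeholder levels are dropped;
#' a covariate left with fewer than two observed levels is skipped with
#' a warning.
#'
#' @param samples_a,samples_b two [sample_table()]s (e.g. the discovery
#'   and validation arms of one group).
#' @return a tibble with `covariate`, `test`, `statistic`, `p_value`.
#' @export
baseline_balance_tests <- function(samples_a, samples_b) {
  if (!nrow(samples_a) || !nrow(samples_b)) abort("both tables must be nonempty")
  if (sd(c(samples_a$age, samples_b$age)) == 0) {
    # degenerate constant ages: no evidence of imbalance
    rows <- list(tibble::tibble(covariate = "age", test = "t",
                                statistic = 0, p_value = 1))
  } else {
    tt <- stats::t.test(samples_a$age, samples_b$age, var.equal = TRUE)
    rows <- list(tibble::tibble(covariate = "age", test = "t",
                                statistic = unname(tt$statistic),
                                p_value = tt$p.value))
  }
  for (cov in c("gender", "control_source", "stage", "histology")) {
    a <- samples_a[[cov]]; b <- samples_b[[cov]]
    keep_a <- a != "none"; keep_b <- b != "none"
    lv <- sort(unique(c(a[keep_a], b[keep_b])))
    if (length(lv) < 2L) {
      warn(sprintf("covariate '%s' has < 2 observed levels; skipped", cov))
      next
    }
    tab <- rbind(table(factor(a[keep_a], lv)), table(factor(b[keep_b], lv)))
    empty <- colSums(tab) == 0
    if (any(empty)) {
      warn(sprintf("dropping empty level(s) of '%s': %s", cov,
                   paste(lv[empty], collapse = ", ")))
      tab <- tab[, !empty, drop = FALSE]
    }
    ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    rows[[length(rows) + 1L]] <- tibble::tibble(
      covariate = cov, test = "chi2",
      statistic = unname(ct$statistic), p_value = ct$p.value)
  }
  dplyr::bind_rows(rows)
}
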