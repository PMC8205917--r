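## ---- internal matrix-level core ----------------------------------------
## X: n x p feature matrix, y: logical (TRUE = case). These helpers avoid
## tibble overhead inside the greedy search's inner loop.

lda_core <- function(X, y, ridge_eps = 1e-8) {
  n1 <- sum(y); n0 <- sum(!y)
  if (n1 < 2L || n0 < 2L) abort("each class needs at least 2 samples")
  p <- ncol(X)
  mu1 <- colMeans(X[y, , drop = FALSE])
  mu0 <- colMeans(X[!y, , drop = FALSE])
  A <- crossprod(sweep(X[y, , drop = FALSE], 2L, mu1)) +
       crossprod(sweep(X[!y, , drop = FALSE], 2L, mu0))
  S <- A / (n1 + n0 - 2L)
  d <- mu1 - mu0
  w <- tryCatch(solve(S, d), error = function(e) NULL)
  ridged <- is.null(w)
  if (ridged) {
    S <- S + diag(ridge_eps * sum(diag(S)) / p, p)
    w <- solve(S, d)
  }
  list(w = w, intercept = -sum(w * (mu1 + mu0)) / 2, ridged = ridged,
       mu1 = mu1, mu0 = mu0, A = A)
}

## Leave-one-out predictions at the midpoint-intercept cutoff 0.
## Each fold is obtained from the full fit by a Sherman-Morrison rank-one
## downdate of the pooled scatter, vectorized over held-out samples;
## degenerate folds (singular scatter, vanishing SM denominator) fall
## back to an explicit refit.
loocv_core <- function(X, y, ridge_eps = 1e-8) {
  n <- nrow(X); p <- ncol(X)
  n1 <- sum(y); n0 <- n - n1
  if (n1 < 3L || n0 < 3L) abort("leave-one-out needs at least 3 samples per class")
  mu1 <- colMeans(X[y, , drop = FALSE])
  mu0 <- colMeans(X[!y, , drop = FALSE])
  Xt <- t(X)                                   # p x n
  mu_own <- matrix(0, p, n)
  mu_own[, y] <- mu1
  mu_own[, !y] <- mu0
  Cdev <- Xt - mu_own                          # x_i - mu_{class(i)}
  A <- tcrossprod(Cdev)                        # pooled scatter
  B <- tryCatch(solve(A), error = function(e) NULL)
  if (is.null(B)) return(loocv_brute(X, y, ridge_eps))

  scl <- ifelse(y, sqrt(n1 / (n1 - 1)), sqrt(n0 / (n0 - 1)))
  U <- Cdev * rep(scl, each = p)
  V <- B %*% U
  g <- 1 - colSums(U * V)

  # leave-one-out class means (only the held-out sample's class changes)
  mu1p <- matrix(mu1, p, n)
  mu0p <- matrix(mu0, p, n)
  mu1p[, y] <- (n1 * mu1 - Xt[, y, drop = FALSE]) / (n1 - 1)
  mu0p[, !y] <- (n0 * mu0 - Xt[, !y, drop = FALSE]) / (n0 - 1)
  D <- mu1p - mu0p
  M <- Xt - (mu1p + mu0p) / 2
  score <- (n - 3) * (colSums((B %*% D) * M) + colSums(V * D) * colSums(V * M) / g)

  bad <- !is.finite(score) | abs(g) < 1e-10
  if (any(bad)) {
    for (i in which(bad)) {
      fit <- lda_core(X[-i, , drop = FALSE], y[-i], ridge_eps)
      score[i] <- sum(fit$w * X[i, ]) + fit$intercept
    }
  }
  score >= 0
}

## reference implementation: explicit refit per fold (also the fallback
## when the pooled scatter of the full data is singular)
loocv_brute <- function(X, y, ridge_eps = 1e-8) {
  vapply(seq_len(nrow(X)), function(i) {
    fit <- lda_core(X[-i, , drop = FALSE], y[-i], ridge_eps)
    sum(fit$w * X[i, ]) + fit$intercept >= 0
  }, logical(1))
}

## fast in-sample AUC (midranks); cases = scores with y TRUE
auc_fast <- function(scores, y) {
  r <- rank(scores)
  n1 <- sum(y); n0 <- length(y) - n1
  (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

expr_features <- function(expr, samples, panel) {
  check_sample_alignment(expr, samples)
  miss <- setdiff(panel, expr_mirnas(expr))
  if (length(miss)) abort(sprintf("miRNA(s) missing from matrix: %s", paste(miss, collapse = ", ")))
  v <- expr_values(expr)[panel, samples$sample_id, drop = FALSE]
  list(X = t(v), y = samples$group == "case")
}

## ---- exported surface ---------------------------------------------------

#' Fit a two-class Fisher linear discriminant
#'
#' Weights are `S_pooled^-1 (mu_case - mu_control)` with the pooled
#' within-class covariance (denominator n - 2); the intercept is the
#' midpoint rule `-w . (mu_case + mu_control) / 2`, so cases score
#' positive on average. A singular pooled covariance triggers a ridge
#' fallback (`1e-8 * trace(S)/p` added to the diagonal) with a warning.
#'
#' @param expr a [mir_expr] of model features (normally log2 scale).
#' @param samples a [sample_table()] giving the case/control labels.
#' @param panel miRNA ids to use as features (default: all).
#' @return an [lda_model()] with cutoff 0 (midpoint rule).
#' @export
fit_fisher_lda <- function(expr, samples, panel = expr_mirnas(expr)) {
  f <- expr_features(expr, samples, panel)
  fit <- lda_core(f$X, f$y)
  if (fit$ridged) warn("singular pooled covariance; ridge fallback applied")
  lda_model(panel, fit$w, fit$intercept, cutoff = 0,
            feature_scale = list(scale = expr_scale(expr)))
}

#' Leave-one-out cross-validated classification metrics
#'
#' Refits the discriminant with each sample held out in turn and
#' classifies the held-out sample at the midpoint-intercept cutoff 0.
#'
#' @inheritParams fit_fisher_lda
#' @return a one-row tibble with `sensitivity`, `specificity`,
#'   `accuracy` and the underlying counts.
#' @export
loocv_metrics <- function(expr, samples, panel = expr_mirnas(expr)) {
  f <- expr_features(expr, samples, panel)
  pred <- loocv_core(f$X, f$y)
  loocv_summary(pred, f$y)
}

loocv_summary <- function(pred, y) {
  tp <- sum(pred & y); tn <- sum(!pred & !y)
  tibble::tibble(tp = tp, fn = sum(y) - tp, tn = tn, fp = sum(!y) - tn,
                 sensitivity = tp / sum(y), specificity = tn / sum(!y),
                 accuracy = (tp + tn) / length(y))
}

#' Greedy forward panel search driven by LOOCV accuracy
#'
#' Grows the panel one miRNA at a time: the size-1 panel is the
#' candidate with the best leave-one-out accuracy; the size-k panel adds
#' the candidate that maximizes the LOOCV accuracy of the union. Ties
#' are broken by higher in-sample AUC, then by lexicographically smaller
#' miRNA id. For each size the trace records the fitted model, LOOCV
#' sensitivity/specificity/accuracy with Wald CIs, the in-sample AUC
#' with its DeLong CI, and the comparison against the previous size
#' (Pearson chi-squared on LOOCV accuracy; paired DeLong test on the
#' in-sample scores).
#'
#' @inheritParams fit_fisher_lda
#' @param candidate_ids candidate miRNA ids (e.g. the kept set of
#'   [robust_filter()]).
#' @param k_max largest panel size to grow to.
#' @return a tibble of class `greedy_trace`, one row per panel size,
#'   with list-columns `panel` and `model`.
#' @export
greedy_search <- function(expr, samples, candidate_ids, k_max = 5) {
  candidate_ids <- sort(unique(as.character(candidate_ids)))
  if (!length(candidate_ids)) abort("no candidate miRNAs")
  if (k_max > length(candidate_ids)) {
    warn(sprintf("k_max truncated from %d to %d candidates", k_max, length(candidate_ids)))
    k_max <- length(candidate_ids)
  }
  f <- expr_features(expr, samples, candidate_ids)
  X <- f$X; y <- f$y
  n <- length(y)
  scale_tag <- expr_scale(expr)

  panel_idx <- integer(0)
  rows <- vector("list", k_max)
  prev <- NULL
  for (k in seq_len(k_max)) {
    pool <- setdiff(seq_along(candidate_ids), panel_idx)
    acc <- vapply(pool, function(j) {
      pred <- loocv_core(X[, c(panel_idx, j), drop = FALSE], y)
      mean(pred == y)
    }, numeric(1))
    top <- pool[acc == max(acc)]
    if (length(top) > 1L) {
      aucs <- vapply(top, function(j) {
        fit <- lda_core(X[, c(panel_idx, j), drop = FALSE], y)
        auc_fast(X[, c(panel_idx, j), drop = FALSE] %*% fit$w, y)
      }, numeric(1))
      top <- top[aucs == max(aucs)]
    }
    pick <- top[1L]   # candidates are in lexicographic order
    panel_idx <- c(panel_idx, pick)

    Xp <- X[, panel_idx, drop = FALSE]
    pred <- loocv_core(Xp, y)
    met <- loocv_summary(pred, y)
    fit <- lda_core(Xp, y)
    scores <- drop(Xp %*% fit$w) + fit$intercept
    roc <- roc_delong(scores, y)
    model <- lda_model(candidate_ids[panel_idx], fit$w, fit$intercept,
                       cutoff = 0, feature_scale = list(scale = scale_tag))

    p_acc <- p_auc <- NA_real_
    if (!is.null(prev)) {
      p_acc <- compare_accuracy_chi2(met$tp + met$tn, n,
                                     prev$met$tp + prev$met$tn, n)$p_value
      p_auc <- delong_test(scores, prev$scores, y)$p_value
    }
    ci <- function(x) wald_ci(x, n)
    rows[[k]] <- tibble::tibble(
      k = k, added = candidate_ids[pick],
      panel = list(candidate_ids[panel_idx]), model = list(model),
      sensitivity = met$sensitivity,
      sens_lo = wald_ci(met$sensitivity, sum(y))[1],
      sens_hi = wald_ci(met$sensitivity, sum(y))[2],
      specificity = met$specificity,
      spec_lo = wald_ci(met$specificity, sum(!y))[1],
      spec_hi = wald_ci(met$specificity, sum(!y))[2],
      accuracy = met$accuracy,
      acc_lo = ci(met$accuracy)[1], acc_hi = ci(met$accuracy)[2],
      n_correct = met$tp + met$tn,
      auc = roc$auc, auc_lo = roc$auc_ci[1], auc_hi = roc$auc_ci[2],
      p_accuracy_vs_prev = p_acc, p_auc_vs_prev = p_auc)
    prev <- list(met = met, scores = scores)
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("greedy_trace", class(out))
  out
}

#' @exportS3Method generics::tidy
tidy.greedy_trace <- function(x, ...) {
  out <- tibble::as_tibble(x)
  out$panel <- vapply(out$panel, paste, character(1), collapse = " + ")
  out$model <- NULL
  out
}

#' @exportS3Method generics::glance
glance.greedy_trace <- function(x, ...) {
  k <- select_model_size(x)
  tibble::tibble(k_max = max(x$k), selected_k = k,
                 accuracy = x$accuracy[x$k == k], auc = x$auc[x$k == k])
}

#' Youden-optimal threshold
#'
#' Maximizes `J = sensitivity + specificity - 1` over the observed
#' scores as candidate thresholds (classify positive when
#' `score >= t`); among ties the smallest threshold is chosen, which
#' maximizes sensitivity.
#'
#' @param scores numeric index values.
#' @param labels logical (`TRUE` = case) or `"case"`/`"control"`.
#' @return the threshold, a single number.
#' @export
youden_cutoff <- function(scores, labels) {
  y <- as_case_logical(labels)
  t_cand <- sort(unique(scores))
  j <- vapply(t_cand, function(t) {
    mean(scores[y] >= t) + mean(scores[!y] < t) - 1
  }, numeric(1))
  t_cand[which.max(j)]   # which.max takes the first (smallest t) on ties
}

#' Recentre a model's cutoff on the Youden-optimal threshold
#'
#' Shifts the intercept by the Youden-optimal threshold of the training
#' scores so that the classification cutoff is exactly 0.
#'
#' @param model an [lda_model()].
#' @param expr,samples the training data the model was fitted on.
#' @return the recentred [lda_model()] (cutoff 0).
#' @export
recenter_youden <- function(model, expr, samples) {
  check_sample_alignment(expr, samples)
  idx <- apply_index(expr, model)
  y <- samples$group[match(idx$sample_id, samples$sample_id)] == "case"
  t_star <- youden_cutoff(idx$index, y)
  lda_model(model$mirna_ids, model$coefficients, model$intercept - t_star,
            cutoff = 0, feature_scale = model$feature_scale)
}

#' Select the panel size from a greedy trace
#'
#' Chooses the largest size `k` whose paired DeLong comparison against
#' size `k - 1` is significant while the step to `k + 1` (if any) is
#' not; if no size qualifies, 1.
#'
#' @param trace a `greedy_trace`.
#' @param alpha two-sided significance level.
#' @return the selected panel size (integer).
#' @export
select_model_size <- function(trace, alpha = 0.05) {
  p <- trace$p_auc_vs_prev
  k_max <- max(trace$k)
  sig <- function(k) !is.na(p[trace$k == k]) && p[trace$k == k] < alpha
  ok <- vapply(trace$k, function(k) {
    k >= 2 && sig(k) && (k == k_max || !sig(k + 1))
  }, logical(1))
  if (!any(ok)) return(1L)
  max(trace$k[ok])
}

as_case_logical <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (!all(labels %in% group_levels)) abort("labels must be 'case'/'control' or logical")
  labels == "case"
}
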