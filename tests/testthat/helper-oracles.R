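# Independent oracles, written as naive reference implementations so the
# code paths they check share nothing with the package internals.

# LOOCV by explicit per-fold refit using textbook formulas only
oracle_loocv <- function(X, y) {
  vapply(seq_len(nrow(X)), function(i) {
    Xi <- X[-i, , drop = FALSE]; yi <- y[-i]
    m1 <- colMeans(Xi[yi, , drop = FALSE])
    m0 <- colMeans(Xi[!yi, , drop = FALSE])
    S <- (cov(Xi[yi, , drop = FALSE]) * (sum(yi) - 1) +
          cov(Xi[!yi, , drop = FALSE]) * (sum(!yi) - 1)) / (length(yi) - 2)
    w <- solve(S, m1 - m0)
    sum(w * X[i, ]) - sum(w * (m1 + m0)) / 2 >= 0
  }, logical(1))
}

# AUC by exhaustive pairwise comparison with the Mann-Whitney kernel
oracle_auc <- function(cases, controls) {
  psi <- outer(cases, controls, function(x, y) (x > y) + 0.5 * (x == y))
  mean(psi)
}

# Youden threshold by exhaustive enumeration over observed scores
oracle_youden <- function(scores, y) {
  cand <- sort(unique(scores))
  j <- sapply(cand, function(t) mean(scores[y] >= t) + mean(scores[!y] < t) - 1)
  best <- which(j == max(j))
  cand[min(best)]
}

# paired bootstrap test of an AUC difference (normal approximation with a
# bootstrap standard error; resampling stratified by class, same indices
# for both modalities)
oracle_bootstrap_delong_p <- function(scores_a, scores_b, y, reps = 10000, seed = 1) {
  set.seed(seed)
  idx_case <- which(y); idx_ctrl <- which(!y)
  d0 <- oracle_auc(scores_a[idx_case], scores_a[idx_ctrl]) -
        oracle_auc(scores_b[idx_case], scores_b[idx_ctrl])
  d <- replicate(reps, {
    ic <- sample(idx_case, replace = TRUE)
    iz <- sample(idx_ctrl, replace = TRUE)
    oracle_auc(scores_a[ic], scores_a[iz]) - oracle_auc(scores_b[ic], scores_b[iz])
  })
  2 * pnorm(-abs(d0 / sd(d)))
}

# small helper: a quick synthetic cohort for pipeline tests
quick_cohort <- function(n = 100, n_mirna = 60, seed = 11, ...) {
  cfg <- cohort_config(n_case = n, n_control = n, n_mirna = n_mirna,
                       seed = seed, ...)
  c(generate_cohort(cfg), list(config = cfg))
}

expr_from_values <- function(v, scale = "log2") mir_expr(v, scale = scale)
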