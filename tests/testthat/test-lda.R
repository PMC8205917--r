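labels_for <- function(y, ids) {
  sample_table(tibble::tibble(
    sample_id = ids, group = ifelse(y, "case", "control"),
    control_source = ifelse(y, "none", "A"), age = 60, gender = "male",
    stage = ifelse(y, "IA", "none"),
    histology = ifelse(y, "differentiated", "none")))
}

feat_expr <- function(X, ids = NULL, mirnas = NULL) {
  ids <- ids %||% sprintf("S%02d", seq_len(nrow(X)))
  mirnas <- mirnas %||% sprintf("m%02d", seq_len(ncol(X)))
  mir_expr(matrix(t(X), ncol = nrow(X), dimnames = list(mirnas, ids)), "log2")
}

test_that("one-dimensional fit matches the closed form", {
  X <- matrix(c(2, 4, 0, 2), ncol = 1)
  y <- c(TRUE, TRUE, FALSE, FALSE)
  m <- fit_fisher_lda(feat_expr(X), labels_for(y, sprintf("S%02d", 1:4)))
  expect_equal(m$coefficients, 1)      # pooled variance 2, mean diff 2
  expect_equal(m$intercept, -2)
  sc <- apply_index(feat_expr(X), m)$index
  expect_equal(sc, c(0, 2, -2, 0))
})

test_that("duplicated features take the ridge path but predict identically", {
  set.seed(3)
  X <- matrix(rnorm(40), ncol = 1)
  y <- rep(c(TRUE, FALSE), each = 20)
  X[y, ] <- X[y, ] + 2
  ids <- sprintf("S%02d", 1:40)
  s <- labels_for(y, ids)
  m1 <- fit_fisher_lda(feat_expr(X), s)
  expect_warning(m2 <- fit_fisher_lda(feat_expr(cbind(X, X)), s), "ridge")
  p1 <- apply_index(feat_expr(X), m1)$predicted
  p2 <- apply_index(feat_expr(cbind(X, X)), m2)$predicted
  expect_identical(p1, p2)
})

test_that("swapping the class labels negates weights, intercept and scores", {
  set.seed(4)
  X <- matrix(rnorm(60), ncol = 2)
  y <- rep(c(TRUE, FALSE), each = 15)
  ids <- sprintf("S%02d", 1:30)
  m <- fit_fisher_lda(feat_expr(X), labels_for(y, ids))
  m_swap <- fit_fisher_lda(feat_expr(X), labels_for(!y, ids))
  expect_equal(m_swap$coefficients, -m$coefficients)
  expect_equal(m_swap$intercept, -m$intercept)
})

test_that("LOOCV equals the brute-force oracle on random small instances", {
  set.seed(10)
  for (r in 1:10) {
    n1 <- sample(5:20, 1); n0 <- sample(5:20, 1); p <- sample(1:3, 1)
    X <- matrix(rnorm((n1 + n0) * p), ncol = p)
    y <- rep(c(TRUE, FALSE), c(n1, n0))
    X[y, ] <- X[y, ] + runif(1, 0, 1.5)
    ids <- sprintf("S%02d", seq_len(n1 + n0))
    met <- loocv_metrics(feat_expr(X), labels_for(y, ids))
    pred <- oracle_loocv(X, y)
    expect_equal(met$accuracy, mean(pred == y))
    expect_equal(met$sensitivity, mean(pred[y]))
    expect_equal(met$specificity, mean(!pred[!y]))
  }
})

test_that("LOOCV is perfect on widely separated data, chance-level on null data", {
  X <- matrix(c(10:19, -(10:19)), ncol = 1)
  y <- rep(c(TRUE, FALSE), each = 10)
  ids <- sprintf("S%02d", 1:20)
  expect_equal(loocv_metrics(feat_expr(X), labels_for(y, ids))$accuracy, 1)
  set.seed(77)
  accs <- replicate(20, {
    Xn <- matrix(rnorm(40), ncol = 1)
    yn <- sample(rep(c(TRUE, FALSE), each = 20))
    loocv_metrics(feat_expr(Xn), labels_for(yn, sprintf("S%02d", 1:40)))$accuracy
  })
  # chance-level on average; single runs spread widely at n = 40 because
  # leave-one-out is pessimistically biased on null data
  expect_gt(mean(accs), 0.4)
  expect_lt(mean(accs), 0.6)
  expect_true(all(accs >= 0.15 & accs <= 0.85))
})

test_that("greedy size-1 equals the exhaustive best single candidate", {
  set.seed(12)
  n <- 30; p <- 8
  X <- matrix(rnorm(n * p), ncol = p)
  y <- rep(c(TRUE, FALSE), each = 15)
  X[y, 3] <- X[y, 3] + 1.5
  ids <- sprintf("S%02d", 1:n)
  mirnas <- sprintf("m%02d", 1:p)
  e <- feat_expr(X, ids, mirnas)
  s <- labels_for(y, ids)
  tr <- greedy_search(e, s, mirnas, k_max = 1)
  best <- vapply(mirnas, function(m) loocv_metrics(e, s, m)$accuracy, numeric(1))
  expect_equal(tr$accuracy[1], max(best))
  expect_true(tr$added[1] %in% names(best)[best == max(best)])
})

test_that("greedy recovers a planted marker among null candidates", {
  hits <- 0L
  for (seed in 1:5) {
    set.seed(seed)
    n <- 100; p <- 30
    X <- matrix(rnorm(n * p), ncol = p)
    y <- rep(c(TRUE, FALSE), each = 50)
    X[y, 7] <- X[y, 7] + 2
    ids <- sprintf("S%03d", 1:n)
    mirnas <- sprintf("m%02d", 1:p)
    tr <- greedy_search(feat_expr(X, ids, mirnas), labels_for(y, ids), mirnas, k_max = 1)
    hits <- hits + (tr$added[1] == "m07")
  }
  expect_gte(hits, 4L)
})

test_that("exact ties fall to the lexicographically smaller id", {
  set.seed(13)
  x <- rnorm(20)
  y <- rep(c(TRUE, FALSE), each = 10)
  x[y] <- x[y] + 2
  X <- cbind(x, x)
  ids <- sprintf("S%02d", 1:20)
  tr <- greedy_search(feat_expr(X, ids, c("m-b", "m-a")), labels_for(y, ids),
                      c("m-b", "m-a"), k_max = 1)
  expect_equal(tr$added[1], "m-a")
})

test_that("candidate ordering does not change the greedy result", {
  ch <- quick_cohort(n = 30, n_mirna = 20, seed = 6)
  feats <- log_transform(normalize_to_controls(
    ch$expression, fit_normalization(ch$expression, ch$config$control_mirna_ids)))
  cands <- setdiff(expr_mirnas(feats), ch$config$control_mirna_ids)
  t1 <- greedy_search(feats, ch$samples, cands, k_max = 3)
  t2 <- greedy_search(feats, ch$samples, rev(cands), k_max = 3)
  expect_identical(t1$panel, t2$panel)
})

test_that("Youden threshold: enumeration example, ties, separation, recentring", {
  scores <- c(1, 2, 3, -3, -2, 1)
  y <- rep(c(TRUE, FALSE), each = 3)
  # J peaks at 2/3 for both t=1 (sens 1, spec 2/3) and t=2 (sens 2/3, spec 1)
  expect_equal(youden_cutoff(scores, y), 1)
  expect_equal(oracle_youden(scores, y), 1)
  # perfect separation: smallest case score
  expect_equal(youden_cutoff(c(5, 6, 7, 1, 2, 3), y), 5)
  set.seed(14)
  for (r in 1:20) {
    sc <- round(rnorm(30), 1)   # rounding forces ties
    yy <- sample(rep(c(TRUE, FALSE), 15))
    expect_equal(youden_cutoff(sc, yy), oracle_youden(sc, yy))
  }
})

test_that("recentring shifts the intercept so the optimal cutoff is zero", {
  set.seed(15)
  X <- matrix(rnorm(60), ncol = 1)
  y <- rep(c(TRUE, FALSE), each = 30)
  X[y, ] <- X[y, ] + 1.5
  ids <- sprintf("S%02d", 1:60)
  e <- feat_expr(X)
  s <- labels_for(y, ids)
  m <- fit_fisher_lda(e, s)
  m2 <- recenter_youden(m, e, s)
  expect_equal(m2$cutoff, 0)
  sc <- apply_index(e, m2)$index
  expect_equal(youden_cutoff(sc, y), 0)
  expect_equal(m2$coefficients, m$coefficients)
})

test_that("model size selection follows the nested DeLong rule", {
  mk_trace <- function(p) {
    structure(tibble::tibble(k = seq_along(p) + 1L - 1L,
                             p_auc_vs_prev = p),
              class = c("greedy_trace", class(tibble::tibble())))
  }
  tr <- mk_trace(c(NA, 1e-6, 0.004, 0.003, 0.33))
  expect_equal(select_model_size(tr), 4L)
  expect_equal(select_model_size(mk_trace(c(NA, 0.2, 0.9, 0.4))), 1L)
  expect_equal(select_model_size(mk_trace(c(NA, 0.001, 0.002, 0.01))), 4L)
})
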