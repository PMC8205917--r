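#' Subset an expression matrix
#'
#' @param expr a [mir_expr].
#' @param sample_ids,mirna_ids ids to keep (default: all).
#' @return a [mir_expr] with the same scale tag.
#' @export
expr_subset <- function(expr, sample_ids = NULL, mirna_ids = NULL) {
  v <- expr_values(expr)
  if (!is.null(mirna_ids)) {
    miss <- setdiff(mirna_ids, rownames(v))
    if (length(miss)) abort(sprintf("miRNA(s) missing: %s", paste(miss, collapse = ", ")))
    v <- v[mirna_ids, , drop = FALSE]
  }
  if (!is.null(sample_ids)) {
    miss <- setdiff(sample_ids, colnames(v))
    if (length(miss)) abort(sprintf("sample(s) missing: %s", paste(miss, collapse = ", ")))
    v <- v[, sample_ids, drop = FALSE]
  }
  mir_expr(v, scale = expr_scale(expr))
}

#' Run the discovery workflow
#'
#' On the discovery split: fit the internal-control normalization
#' (freezing the reference level), check control stability (warning when
#' any M exceeds 1), apply the robust filter, log2-transform, run the
#' greedy forward LDA search, pick the panel size by paired DeLong
#' comparisons, and recentre the selected model's cutoff on the Youden
#' threshold. The returned model carries the normalization provenance in
#' `feature_scale`, so it can be applied to new raw cohorts without
#' re-estimating anything.
#'
#' @param expr a raw-scale [mir_expr] for the whole cohort.
#' @param samples a [sample_table()] with `split` assigned.
#' @param control_ids the three internal-control miRNA ids.
#' @param k_max largest panel size to consider.
#' @param alpha significance level for model-size selection.
#' @param signal_threshold,sample_fraction,group_rule robust-filter
#'   settings (see [robust_filter()]).
#' @param out_dir optional directory; if given, writes `model.json`,
#'   `trace.tsv` and `log.txt`.
#' @return a list of class `discovery_fit`: `model` (Youden-recentred
#'   [lda_model()]), `trace` (the greedy search trace), `selected_k`,
#'   `norm_spec`, `stability`, `filter`, `log`.
#' @export
run_discovery <- function(expr, samples, control_ids, k_max = 5, alpha = 0.05,
                          signal_threshold = 64, sample_fraction = 0.5,
                          group_rule = "each_group", out_dir = NULL) {
  samples <- sample_table(samples)
  disc <- dplyr::filter(samples, .data$split == "discovery")
  if (!nrow(disc)) abort("no samples assigned to the discovery split")
  if (length(unique(disc$group)) < 2L) abort("discovery split needs both groups")
  e <- expr_subset(expr, sample_ids = disc$sample_id)
  log <- character()
  say <- function(...) {
    msg <- sprintf(...)
    log <<- c(log, msg)
    rlang::inform(msg)
  }
  say("discovery split: %d cases, %d controls, %d miRNAs",
      sum(disc$group == "case"), sum(disc$group == "control"), nrow(e))

  norm_spec <- fit_normalization(e, control_ids)
  say("normalization reference level frozen at %.4f", norm_spec$reference_level)
  stab <- control_stability(e, control_ids)
  if (any(stab$m_value > 1)) {
    warn(sprintf("unstable internal control(s): %s",
                 paste(stab$mirna_id[stab$m_value > 1], collapse = ", ")))
  }
  say("control stability M: %s",
      paste(sprintf("%s=%.3f", stab$mirna_id, stab$m_value), collapse = ", "))

  norm <- normalize_to_controls(e, norm_spec)
  filt <- robust_filter(norm, disc, signal_threshold, sample_fraction,
                        group_rule, exclude = control_ids)
  candidates <- filt$mirna_id[filt$kept]
  say("robust filter kept %d of %d candidate miRNAs", length(candidates), nrow(filt))
  if (length(candidates) < 2L) {
    abort("fewer than 2 miRNAs survive the robust filter; relax signal_threshold or sample_fraction")
  }

  feats <- log_transform(norm)
  trace <- greedy_search(feats, disc, candidates, k_max)
  selected_k <- select_model_size(trace, alpha)
  say("selected panel size %d (alpha = %g): %s", selected_k, alpha,
      paste(trace$panel[[selected_k]], collapse = " + "))

  model <- recenter_youden(trace$model[[selected_k]], feats, disc)
  model <- lda_model(model$mirna_ids, model$coefficients, model$intercept,
                     cutoff = 0,
                     feature_scale = list(scale = "log2",
                                          control_ids = norm_spec$control_ids,
                                          reference_level = norm_spec$reference_level))
  fit <- structure(list(model = model, trace = trace, selected_k = selected_k,
                        norm_spec = norm_spec, stability = stab, filter = filt,
                        log = log),
                   class = "discovery_fit")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_model(model, file.path(out_dir, "model.json"))
    readr::write_tsv(tidy(trace), file.path(out_dir, "trace.tsv"), progress = FALSE)
    writeLines(log, file.path(out_dir, "log.txt"))
  }
  fit
}

#' @export
print.discovery_fit <- function(x, ...) {
  cat("Discovery fit\n")
  cat(x$log, sep = "\n")
  print(x$model)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.discovery_fit <- function(x, ...) tidy(x$trace)

#' @exportS3Method generics::glance
glance.discovery_fit <- function(x, ...) {
  r <- x$trace[x$trace$k == x$selected_k, ]
  tibble::tibble(selected_k = x$selected_k, accuracy = r$accuracy, auc = r$auc,
                 n_candidates = sum(x$filter$kept))
}

model_norm_spec <- function(model) {
  fs <- model$feature_scale
  if (is.null(fs$control_ids) || is.null(fs$reference_level)) {
    abort("model carries no normalization provenance; pass a discovery_fit")
  }
  normalization_spec(fs$control_ids, fs$reference_level)
}

#' Validate a fitted index on held-out samples
#'
#' Applies the frozen normalization and the fitted model to the
#' validation split only, and assembles the full validation report:
#' ROC/AUC with DeLong CI, confusion metrics at the model cutoff,
#' specificity per control source, sensitivity per stage and histology,
#' predictive values at a screening prevalence, and the per-sample index
#' table every metric can be recomputed from.
#'
#' @param fit a `discovery_fit`, or an [lda_model()] whose
#'   `feature_scale` carries the normalization provenance.
#' @param expr a raw-scale [mir_expr] for the whole cohort.
#' @param samples a [sample_table()] with `split` assigned; rows with
#'   `split == "validation"` are used.
#' @param prevalence disease prevalence for the predictive values
#'   (default 0.742%, a gastric-cancer screening population).
#' @return a list of class `validation_report`.
#' @export
run_validation <- function(fit, expr, samples, prevalence = 0.00742) {
  model <- if (inherits(fit, "discovery_fit")) fit$model else fit
  stopifnot(inherits(model, "lda_model"))
  norm_spec <- if (inherits(fit, "discovery_fit")) fit$norm_spec else model_norm_spec(model)
  assert_scalar_number(prevalence, "prevalence", 0, 1)
  samples <- sample_table(samples)
  val <- dplyr::filter(samples, .data$split == "validation")
  if (!nrow(val)) abort("no samples assigned to the validation split")
  e <- expr_subset(expr, sample_ids = val$sample_id)
  feats <- log_transform(normalize_to_controls(e, norm_spec))
  idx <- apply_index(feats, model)
  per_sample <- dplyr::left_join(idx, val, by = "sample_id")
  y <- per_sample$group == "case"

  roc <- roc_delong(per_sample$index, y)
  conf <- confusion_at_cutoff(per_sample$index, y, model$cutoff)
  pv <- predictive_values(conf$sensitivity, conf$specificity, prevalence)

  subgroup <- function(rows, label_col, metric) {
    dplyr::summarise(
      dplyr::group_by(rows, .data[[label_col]]),
      n = dplyr::n(),
      value = if (metric == "sensitivity") mean(.data$predicted == "case")
              else mean(.data$predicted == "control"),
      .groups = "drop")
  }
  ctrls <- per_sample[!y, ]
  cases <- per_sample[y, ]
  by_source <- subgroup(ctrls, "control_source", "specificity")
  names(by_source)[3] <- "specificity"
  by_stage <- subgroup(cases, "stage", "sensitivity")
  names(by_stage)[3] <- "sensitivity"
  by_histology <- subgroup(cases, "histology", "sensitivity")
  names(by_histology)[3] <- "sensitivity"

  structure(list(model = model, roc = roc, confusion = conf,
                 by_source = by_source, by_stage = by_stage,
                 by_histology = by_histology,
                 predictive = pv, prevalence = prevalence,
                 samples = per_sample),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("Validation report\n")
  print(x$roc)
  cat(sprintf("  sensitivity %.3f (%.3f-%.3f)  specificity %.3f (%.3f-%.3f)  accuracy %.3f\n",
              x$confusion$sensitivity, x$confusion$sens_lo, x$confusion$sens_hi,
              x$confusion$specificity, x$confusion$spec_lo, x$confusion$spec_hi,
              x$confusion$accuracy))
  cat(sprintf("  PPV %.3f / NPV %.4f at prevalence %.3f%%\n",
              x$predictive$ppv, x$predictive$npv, 100 * x$prevalence))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.validation_report <- function(x, ...) x$samples

#' @exportS3Method generics::glance
glance.validation_report <- function(x, ...) {
  tibble::tibble(auc = x$roc$auc, auc_lo = x$roc$auc_ci[1], auc_hi = x$roc$auc_ci[2],
                 sensitivity = x$confusion$sensitivity,
                 specificity = x$confusion$specificity,
                 accuracy = x$confusion$accuracy,
                 ppv = x$predictive$ppv, npv = x$predictive$npv,
                 prevalence = x$prevalence)
}

standardize_features <- function(expr, panel) {
  v <- expr_values(expr)[panel, , drop = FALSE]
  sds <- apply(v, 1L, sd)
  if (any(sds == 0)) {
    warn(sprintf("dropping zero-variance miRNA(s): %s",
                 paste(rownames(v)[sds == 0], collapse = ", ")))
    v <- v[sds > 0, , drop = FALSE]
    sds <- sds[sds > 0]
  }
  if (nrow(v) < 2L) abort("need at least 2 panel miRNAs with variance")
  (v - rowMeans(v)) / sds
}

#' Unsupervised clustering of samples on a panel
#'
#' Standardizes each panel miRNA to mean 0 / sd 1, clusters the samples
#' agglomeratively with Pearson dissimilarity (1 - correlation) and
#' Ward linkage, cuts at two clusters and reports the best-permutation
#' agreement with the true case/control labels.
#'
#' @param expr a [mir_expr] of model features.
#' @param samples a [sample_table()] for the same samples.
#' @param panel panel miRNA ids (>= 2).
#' @return a list with `order` (sample ids in dendrogram order),
#'   `clusters` (tibble `sample_id`, `cluster`), `agreement`, and the
#'   `hclust` object.
#' @export
cluster_summary <- function(expr, samples, panel) {
  check_sample_alignment(expr, samples)
  z <- standardize_features(expr, panel)
  d <- stats::as.dist(1 - stats::cor(z))
  hc <- stats::hclust(d, method = "ward.D2")
  cl <- stats::cutree(hc, k = 2L)
  y <- samples$group[match(colnames(z), samples$sample_id)] == "case"
  agreement <- max(mean((cl == 1L) == y), mean((cl == 2L) == y))
  list(order = colnames(z)[hc$order],
       clusters = tibble::tibble(sample_id = colnames(z), cluster = unname(cl)),
       agreement = agreement, hclust = hc)
}

#' Principal components of a standardized panel
#'
#' Eigendecomposition of the correlation structure of the panel
#' features (each miRNA standardized to mean 0 / sd 1): per-component
#' explained-variance fractions (summing to 1) and sample coordinates on
#' the first three components (fewer when the panel is smaller).
#'
#' @param expr a [mir_expr] of model features (>= 3 samples).
#' @param panel panel miRNA ids (>= 2).
#' @return a list with `explained` (tibble `component`,
#'   `variance_fraction`), `coords` (sample coordinates), and
#'   `top3_variance` (summed fraction of the first <= 3 components).
#' @export
pca_summary <- function(expr, panel) {
  z <- standardize_features(expr, panel)
  if (ncol(z) < 3L) abort("need at least 3 samples")
  pc <- stats::prcomp(t(z), center = FALSE, scale. = FALSE)
  fr <- pc$sdev^2 / sum(pc$sdev^2)
  k <- min(3L, length(fr))
  coords <- tibble::as_tibble(pc$x[, seq_len(k), drop = FALSE])
  coords <- dplyr::bind_cols(tibble::tibble(sample_id = colnames(z)), coords)
  list(explained = tibble::tibble(component = seq_along(fr), variance_fraction = fr),
       coords = coords, top3_variance = sum(fr[seq_len(k)]))
}
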