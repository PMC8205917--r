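#' Stability of internal-control miRNAs
#'
#' geNorm-style M statistic: for control `j`, `M_j` is the mean over the
#' other controls `k` of the standard deviation across samples of
#' `log2(x_j / x_k)`. A perfectly stable pair has a constant log-ratio
#' and contributes 0; lower M means more stable. M is invariant to
#' sample-wide multiplicative factors, which scale all controls of a
#' sample together.
#'
#' @param expr a raw-scale [mir_expr].
#' @param control_ids at least two control miRNA ids present in `expr`.
#' @return a tibble with `mirna_id` and `m_value`.
#' @export
control_stability <- function(expr, control_ids) {
  if (length(control_ids) < 2L) abort("need at least 2 control miRNAs")
  miss <- setdiff(control_ids, expr_mirnas(expr))
  if (length(miss)) abort(sprintf("control miRNA(s) missing: %s", paste(miss, collapse = ", ")))
  v <- expr_values(expr)[control_ids, , drop = FALSE]
  if (any(v <= 0)) abort("control miRNAs must have strictly positive signal")
  lv <- log2(v)
  m <- vapply(seq_along(control_ids), function(j) {
    others <- setdiff(seq_along(control_ids), j)
    mean(vapply(others, function(k) sd(lv[j, ] - lv[k, ]), numeric(1)))
  }, numeric(1))
  tibble::tibble(mirna_id = control_ids, m_value = m)
}

#' Internal-control normalization
#'
#' Per-sample multiplicative rescaling so that the arithmetic mean of
#' the three internal-control miRNAs equals a fixed `reference_level` in
#' every sample. The reference is estimated once (grand mean of the
#' per-sample control means, typically on the discovery set via
#' [fit_normalization()]) and frozen, so later cohorts are rescaled to
#' the same level and the raw-scale filter threshold keeps its meaning.
#'
#' @param control_ids exactly three internal-control miRNA ids.
#' @param reference_level positive target for the per-sample control mean.
#' @return an object of class `normalization_spec`.
#' @export
normalization_spec <- function(control_ids, reference_level) {
  if (length(control_ids) != 3L) abort("exactly 3 control miRNAs required")
  assert_scalar_number(reference_level, "reference_level", lo = .Machine$double.xmin)
  structure(list(control_ids = as.character(control_ids),
                 reference_level = reference_level),
            class = "normalization_spec")
}

#' @rdname normalization_spec
#' @param expr a raw-scale [mir_expr] (the discovery data).
#' @export
fit_normalization <- function(expr, control_ids) {
  miss <- setdiff(control_ids, expr_mirnas(expr))
  if (length(miss)) abort(sprintf("control miRNA(s) missing: %s", paste(miss, collapse = ", ")))
  v <- expr_values(expr)[control_ids, , drop = FALSE]
  normalization_spec(control_ids, mean(colMeans(v)))
}

#' @rdname normalization_spec
#' @param spec a `normalization_spec`.
#' @return `normalize_to_controls()`: a [mir_expr] with scale
#'   `"normalized"`.
#' @export
normalize_to_controls <- function(expr, spec) {
  stopifnot(inherits(spec, "normalization_spec"))
  # accepting normalized input makes the operation idempotent under a
  # frozen reference (the per-sample factor is then exactly 1)
  if (expr_scale(expr) == "log2") abort("normalize_to_controls() expects signal-scale input")
  miss <- setdiff(spec$control_ids, expr_mirnas(expr))
  if (length(miss)) abort(sprintf("control miRNA(s) missing: %s", paste(miss, collapse = ", ")))
  v <- expr_values(expr)
  ctrl_mean <- colMeans(v[spec$control_ids, , drop = FALSE])
  if (any(ctrl_mean <= 0)) {
    abort(sprintf("zero/negative control mean in sample(s): %s",
                  paste(names(ctrl_mean)[ctrl_mean <= 0], collapse = ", ")))
  }
  mir_expr(sweep(v, 2L, spec$reference_level / ctrl_mean, `*`), scale = "normalized")
}

#' Robust expression filter
#'
#' Keeps a miRNA when the fraction of samples with normalized signal
#' strictly above `signal_threshold` is strictly above `sample_fraction`
#' — evaluated within the case and control groups and combined with
#' `group_rule` (`"each_group"`: must pass in both; `"any_group"`:
#' either suffices). Internal-control miRNAs should be passed via
#' `exclude` so they never become panel candidates.
#'
#' @param expr a normalized-scale [mir_expr].
#' @param samples a [sample_table()] covering the same samples.
#' @param signal_threshold raw-scale signal cutoff (default 64).
#' @param sample_fraction required fraction of samples (default 0.5).
#' @param group_rule `"each_group"` (default) or `"any_group"`.
#' @param exclude miRNA ids barred from candidacy.
#' @return a tibble with `mirna_id`, `frac_case`, `frac_control`, `kept`,
#'   one row per non-excluded miRNA.
#' @export
robust_filter <- function(expr, samples, signal_threshold = 64,
                          sample_fraction = 0.5,
                          group_rule = c("each_group", "any_group"),
                          exclude = character()) {
  group_rule <- match.arg(group_rule)
  assert_scalar_number(signal_threshold, "signal_threshold", lo = .Machine$double.xmin)
  if (!(sample_fraction > 0 && sample_fraction < 1)) abort("sample_fraction must be in (0,1)")
  if (expr_scale(expr) != "normalized") abort("robust_filter() expects normalized input")
  check_sample_alignment(expr, samples)
  v <- expr_values(expr)
  keep_rows <- !rownames(v) %in% exclude
  v <- v[keep_rows, , drop = FALSE]
  case_ids <- samples$sample_id[samples$group == "case"]
  ctrl_ids <- samples$sample_id[samples$group == "control"]
  if (!length(case_ids) || !length(ctrl_ids)) abort("both groups must be nonempty")
  frac_case <- rowMeans(v[, case_ids, drop = FALSE] > signal_threshold)
  frac_ctrl <- rowMeans(v[, ctrl_ids, drop = FALSE] > signal_threshold)
  pass_case <- frac_case > sample_fraction
  pass_ctrl <- frac_ctrl > sample_fraction
  kept <- if (group_rule == "each_group") pass_case & pass_ctrl else pass_case | pass_ctrl
  tibble::tibble(mirna_id = rownames(v), frac_case = unname(frac_case),
                 frac_control = unname(frac_ctrl), kept = unname(kept))
}

#' Log2 feature transform
#'
#' `log2(max(value, 1))` on a normalized matrix: the floor at 1 keeps
#' features non-negative and bounds the influence of signals near the
#' detection floor. This is the feature scale on which discriminant
#' models are fitted.
#'
#' @param expr a normalized-scale [mir_expr].
#' @return a [mir_expr] with scale `"log2"`.
#' @export
log_transform <- function(expr) {
  if (expr_scale(expr) != "normalized") abort("log_transform() expects normalized input")
  mir_expr(log2(pmax(expr_values(expr), 1)), scale = "log2")
}
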