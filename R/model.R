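#' Linear discriminant diagnostic index
#'
#' The fitted object behind a serum-miRNA diagnostic index: an ordered
#' miRNA panel, one coefficient per member, an intercept, and a
#' classification cutoff (0 by convention once the intercept has been
#' recentred on the Youden-optimal threshold). `feature_scale` records
#' the scale the coefficients apply to — the expression scale tag plus,
#' when normalization provenance is known, the internal-control ids and
#' the frozen reference level — so a model cannot silently be applied to
#' un-normalized data.
#'
#' A sample's index is `sum(coefficients * features) + intercept`; it is
#' classified as a case when the index is greater than or equal to the
#' cutoff (ties go to "case": in a screening context the boundary
#' favours sensitivity).
#'
#' @param mirna_ids character panel, length >= 1.
#' @param coefficients numeric, one per panel member.
#' @param intercept,cutoff numeric scalars.
#' @param feature_scale a list with at least `$scale` (one of `"raw"`,
#'   `"normalized"`, `"log2"`); optionally `$control_ids` and
#'   `$reference_level`.
#' @return an object of class `lda_model`.
#' @examples
#' egc <- lda_model(c("miR-4257", "miR-6785-5p", "miR-187-5p", "miR-5739"),
#'                  c(2.06054, -1.25451, 0.834875, -1.07189), -4.4385)
#' egc
#' @export
lda_model <- function(mirna_ids, coefficients, intercept, cutoff = 0,
                      feature_scale = list(scale = "log2")) {
  mirna_ids <- as.character(mirna_ids)
  coefficients <- as.numeric(coefficients)
  intercept <- as.numeric(intercept)
  cutoff <- as.numeric(cutoff)
  if (length(mirna_ids) < 1L) abort("panel must contain at least one miRNA")
  if (anyDuplicated(mirna_ids)) abort("duplicate miRNA in panel")
  if (length(coefficients) != length(mirna_ids)) {
    abort_format(sprintf("%d miRNAs but %d coefficients",
                         length(mirna_ids), length(coefficients)))
  }
  assert_scalar_number(intercept, "intercept")
  assert_scalar_number(cutoff, "cutoff")
  if (is.null(feature_scale$scale) ||
      !feature_scale$scale %in% c("raw", "normalized", "log2")) {
    abort_format("feature_scale$scale must be raw/normalized/log2")
  }
  structure(list(mirna_ids = mirna_ids, coefficients = coefficients,
                 intercept = intercept, cutoff = cutoff,
                 feature_scale = feature_scale),
            class = "lda_model")
}

#' @export
print.lda_model <- function(x, ...) {
  terms <- sprintf("(%g) x %s", x$coefficients, x$mirna_ids)
  cat("Linear discriminant index (", length(x$mirna_ids), " miRNAs, ",
      x$feature_scale$scale, " features)\n  ", sep = "")
  cat(paste(terms, collapse = " + "), sprintf("%+g", x$intercept), "\n")
  cat("  classify case when index >=", x$cutoff, "\n")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.lda_model <- function(x, ...) {
  tibble::tibble(term = c(x$mirna_ids, "(Intercept)"),
                 estimate = c(x$coefficients, x$intercept))
}

#' @exportS3Method generics::glance
glance.lda_model <- function(x, ...) {
  tibble::tibble(n_mirna = length(x$mirna_ids), cutoff = x$cutoff,
                 feature_scale = x$feature_scale$scale)
}

#' Save / load a model as JSON
#'
#' Keys: `mirna_ids`, `coefficients`, `intercept`, `cutoff`,
#' `feature_scale`. `read_model(write_model(m))` is the identity.
#'
#' @param model an [lda_model()].
#' @param path file path.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "lda_model"))
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("mirna_ids", "coefficients", "intercept", "cutoff", "feature_scale")
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    abort_format(sprintf("model file missing key(s): %s", paste(miss, collapse = ", ")))
  }
  lda_model(x$mirna_ids, x$coefficients, x$intercept, x$cutoff,
            as.list(x$feature_scale))
}

#' Score samples with a fitted index
#'
#' Computes the linear index for every sample of an expression matrix on
#' the model's feature scale and classifies at the model cutoff.
#'
#' @param expr a [mir_expr] whose scale tag matches
#'   `model$feature_scale$scale`.
#' @param model an [lda_model()].
#' @return a tibble with `sample_id`, `index`, `predicted`
#'   (`"case"`/`"control"`).
#' @export
apply_index <- function(expr, model) {
  stopifnot(inherits(model, "lda_model"))
  if (expr_scale(expr) != model$feature_scale$scale) {
    abort(sprintf("feature scale mismatch: matrix is '%s', model expects '%s'",
                  expr_scale(expr), model$feature_scale$scale))
  }
  miss <- setdiff(model$mirna_ids, expr_mirnas(expr))
  if (length(miss)) {
    abort(sprintf("miRNA(s) missing from matrix: %s", paste(miss, collapse = ", ")))
  }
  v <- expr_values(expr)[model$mirna_ids, , drop = FALSE]
  idx <- unname(drop(crossprod(v, model$coefficients)) + model$intercept)
  tibble::tibble(sample_id = expr_samples(expr),
                 index = idx,
                 predicted = ifelse(idx >= model$cutoff, "case", "control"))
}
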