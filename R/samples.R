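#' Per-sample metadata
#'
#' A sample table is a tibble with one row per serum sample and columns
#' `sample_id`, `group` (`case`/`control`), `control_source`
#' (`A`/`B`/`C`/`none` — the three recruitment sources of the non-cancer
#' controls), `age` (years), `gender` (`male`/`female`), `stage`
#' (`IA`/`IB`/`II`/`none`), `histology`
#' (`differentiated`/`undifferentiated`/`special`/`none`) and `split`
#' (`discovery`/`validation`/`unassigned`). Cases carry
#' `control_source = "none"`; controls carry `stage = histology =
#' "none"`.
#'
#' @param x a data frame with the columns above (`split` optional,
#'   defaults to `"unassigned"`).
#' @return a validated tibble.
#' @export
sample_table <- function(x) {
  x <- tibble::as_tibble(x)
  need <- c("sample_id", "group", "control_source", "age", "gender",
            "stage", "histology")
  miss <- setdiff(need, names(x))
  if (length(miss)) abort_format(sprintf("missing column(s): %s", paste(miss, collapse = ", ")))
  if (!"split" %in% names(x)) x$split <- "unassigned"
  x$sample_id <- as.character(x$sample_id)
  dup <- unique(x$sample_id[duplicated(x$sample_id)])
  if (length(dup)) abort_format(sprintf("duplicate sample_id: %s", paste(dup, collapse = ", ")))

  check_levels <- function(col, levels) {
    bad <- setdiff(unique(x[[col]]), levels)
    if (length(bad)) {
      abort_format(sprintf("invalid %s value(s): %s (allowed: %s)",
                           col, paste(bad, collapse = ", "),
                           paste(levels, collapse = ", ")))
    }
  }
  # a case with stage/histology left blank is recoverable; fill as none
  is_case <- x$group == "case"
  for (col in c("stage", "histology")) {
    blank <- is.na(x[[col]]) | x[[col]] == ""
    if (any(blank & is_case)) {
      warn(sprintf("%d case(s) with missing %s filled as 'none'", sum(blank & is_case), col))
    }
    x[[col]][blank] <- "none"
  }
  x$control_source[is.na(x$control_source) | x$control_source == ""] <- "none"
  check_levels("group", group_levels)
  check_levels("control_source", control_source_levels)
  check_levels("gender", c("male", "female"))
  check_levels("stage", stage_levels)
  check_levels("histology", histology_levels)
  check_levels("split", split_levels)
  if (!is.numeric(x$age)) abort_format("age must be numeric")

  bad <- is_case & x$control_source != "none"
  if (any(bad)) {
    abort_format(sprintf("case sample(s) with a control_source: %s",
                         paste(x$sample_id[bad], collapse = ", ")))
  }
  bad <- !is_case & (x$stage != "none" | x$histology != "none")
  if (any(bad)) {
    abort_format(sprintf("control sample(s) with stage/histology set: %s",
                         paste(x$sample_id[bad], collapse = ", ")))
  }
  x
}

#' Read / write sample metadata tables
#'
#' Tab-separated with a named header; categorical columns are validated
#' against their allowed levels (see [sample_table()]).
#'
#' @param path file path.
#' @export
read_sample_table <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(
    sample_id = "c", group = "c", control_source = "c", age = "d",
    gender = "c", stage = "c", histology = "c", .default = "c"),
    progress = FALSE)
  sample_table(x)
}

#' @rdname read_sample_table
#' @param x a sample table.
#' @export
write_sample_table <- function(x, path) {
  readr::write_tsv(sample_table(x), path, progress = FALSE)
  invisible(path)
}

#' Check that an expression matrix and a sample table describe the same samples
#'
#' Errors with the symmetric difference if the sample sets disagree.
#'
#' @param expr a [mir_expr].
#' @param samples a [sample_table()].
#' @return invisibly `TRUE`.
#' @export
check_sample_alignment <- function(expr, samples) {
  a <- expr_samples(expr)
  b <- samples$sample_id
  only_expr <- setdiff(a, b)
  only_meta <- setdiff(b, a)
  if (length(only_expr) || length(only_meta)) {
    abort_format(sprintf(
      "sample mismatch; only in matrix: {%s}; only in metadata: {%s}",
      paste(only_expr, collapse = ", "), paste(only_meta, collapse = ", ")))
  }
  invisible(TRUE)
}
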