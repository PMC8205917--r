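#' Expression matrix container
#'
#' A `mir_expr` is a wide tibble holding microarray signal intensities:
#' the first column `mirna_id` identifies the miRNA, every remaining
#' column is one sample. A scale tag (`"raw"`, `"normalized"` or
#' `"log2"`) travels with the object (and with its on-disk form) so that
#' a fitted model can refuse to score data on the wrong scale.
#'
#' @param x a data frame whose first column is `mirna_id` (character)
#'   followed by one numeric column per sample, or a numeric matrix with
#'   miRNA rownames and sample colnames.
#' @param scale one of `"raw"`, `"normalized"`, `"log2"`.
#' @return a tibble of class `mir_expr` with attribute `mir_scale`.
#' @examples
#' m <- matrix(c(64, 10, 128, 20), nrow = 2,
#'             dimnames = list(c("miR-a", "miR-b"), c("S1", "S2")))
#' mir_expr(m)
#' @export
mir_expr <- function(x, scale = c("raw", "normalized", "log2")) {
  scale <- match.arg(scale)
  if (is.matrix(x)) {
    if (is.null(rownames(x)) || is.null(colnames(x))) {
      abort("matrix input needs miRNA rownames and sample colnames")
    }
    dup <- unique(colnames(x)[duplicated(colnames(x))])
    if (length(dup)) {
      abort_format(sprintf("duplicate sample id: %s", paste(dup, collapse = ", ")))
    }
    x <- tibble::as_tibble(x, rownames = "mirna_id")
  }
  x <- tibble::as_tibble(x)
  if (ncol(x) < 2L) abort("expression table needs a mirna_id column and at least one sample")
  names(x)[1L] <- "mirna_id"
  x$mirna_id <- as.character(x$mirna_id)
  out <- structure(x, mir_scale = scale,
                   class = c("mir_expr", class(tibble::tibble())))
  validate_mir_expr(out)
  out
}

validate_mir_expr <- function(x) {
  dup <- unique(x$mirna_id[duplicated(x$mirna_id)])
  if (length(dup)) {
    abort_format(sprintf("duplicate mirna_id: %s", paste(dup, collapse = ", ")))
  }
  sn <- names(x)[-1L]
  dup <- unique(sn[duplicated(sn)])
  if (length(dup)) {
    abort_format(sprintf("duplicate sample id: %s", paste(dup, collapse = ", ")))
  }
  v <- as.matrix(x[-1L])
  if (!is.numeric(v)) abort_format("sample columns must be numeric")
  if (any(!is.finite(v))) abort_format("expression values must be finite")
  if (expr_scale(x) %in% c("raw", "normalized") && any(v < 0)) {
    abort_format(sprintf("%s-scale values must be non-negative", expr_scale(x)))
  }
  invisible(x)
}

#' @rdname mir_expr
#' @export
expr_scale <- function(x) attr(x, "mir_scale") %||% "raw"

set_expr_scale <- function(x, scale) {
  attr(x, "mir_scale") <- scale
  x
}

#' @rdname mir_expr
#' @export
expr_values <- function(x) {
  v <- as.matrix(x[-1L])
  rownames(v) <- x$mirna_id
  v
}

#' @rdname mir_expr
#' @export
expr_mirnas <- function(x) x$mirna_id

#' @rdname mir_expr
#' @export
expr_samples <- function(x) names(x)[-1L]

#' @export
print.mir_expr <- function(x, ...) {
  cat(sprintf("# miRNA expression: %d miRNAs x %d samples, scale = %s\n",
              nrow(x), ncol(x) - 1L, expr_scale(x)))
  NextMethod()
}

#' Read / write expression matrices
#'
#' Tab-separated text: first column the miRNA id, header row the sample
#' ids. An optional first line `#scale=raw|normalized|log2` declares the
#' scale tag (default `raw`); [write_expression_matrix()] always emits
#' it. Values round-trip exactly (doubles are written with a
#' shortest-round-trip representation).
#'
#' @param path file path.
#' @return a [mir_expr].
#' @export
read_expression_matrix <- function(path) {
  first <- readLines(path, n = 1L)
  scale <- "raw"
  skip <- 0L
  if (startsWith(first, "#")) {
    skip <- 1L
    m <- regmatches(first, regexec("^#scale=(\\w+)", first))[[1L]]
    if (length(m) == 2L) {
      if (!m[2L] %in% c("raw", "normalized", "log2")) {
        abort_format(sprintf("unknown scale tag '%s'", m[2L]))
      }
      scale <- m[2L]
    }
  }
  raw <- readr::read_tsv(path, skip = skip, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (ncol(raw) < 2L) abort_format("expression file needs an id column and >= 1 sample")
  ids <- as.character(raw[[1L]])
  vals <- raw[-1L]
  for (j in seq_along(vals)) {
    num <- suppressWarnings(as.numeric(vals[[j]]))
    bad <- which(is.na(num) & !is.na(vals[[j]]))
    if (length(bad)) {
      abort_format(sprintf(
        "non-numeric value '%s' at row '%s', column '%s'",
        vals[[j]][bad[1L]], ids[bad[1L]], names(vals)[j]))
    }
    vals[[j]] <- num
  }
  mir_expr(tibble::tibble(mirna_id = ids, !!!vals), scale = scale)
}

#' @rdname read_expression_matrix
#' @param x a [mir_expr].
#' @export
write_expression_matrix <- function(x, path) {
  stopifnot(inherits(x, "mir_expr"))
  writeLines(sprintf("#scale=%s", expr_scale(x)), path)
  readr::write_tsv(tibble::as_tibble(unclass_expr(x)), path, append = TRUE,
                   col_names = TRUE, progress = FALSE)
  invisible(path)
}

unclass_expr <- function(x) {
  class(x) <- setdiff(class(x), "mir_expr")
  attr(x, "mir_scale") <- NULL
  x
}
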