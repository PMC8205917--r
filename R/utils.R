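#' @importFrom rlang abort warn %||%
#' @importFrom stats sd var qnorm pnorm pchisq setNames
NULL

# stop with a classed condition so tests can target specific failures
abort_format <- function(msg, class = "mirpanel_format_error") {
  abort(msg, class = class)
}

assert_scalar_number <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lo || x > hi) {
    abort(sprintf("`%s` must be a single finite number in [%s, %s]", name, lo, hi))
  }
  invisible(x)
}

group_levels <- c("case", "control")
control_source_levels <- c("A", "B", "C", "none")
stage_levels <- c("IA", "IB", "II", "none")
histology_levels <- c("differentiated", "undifferentiated", "special", "none")
split_levels <- c("discovery", "validation", "unassigned")
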