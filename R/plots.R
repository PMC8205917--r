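#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_abline geom_point
#'   geom_jitter geom_hline labs theme_minimal position_jitter
NULL

#' @exportS3Method ggplot2::autoplot
autoplot.roc_result <- function(object, ...) {
  ggplot(object$curve, aes(x = .data$fpr, y = .data$tpr)) +
    geom_abline(slope = 1, intercept = 0, linetype = "dashed", colour = "grey60") +
    geom_line(linewidth = 0.8, colour = "#2166AC") +
    labs(x = "1 - specificity", y = "Sensitivity",
         title = sprintf("AUC %.3f (95%% CI %.3f-%.3f)",
                         object$auc, object$auc_ci[1], object$auc_ci[2])) +
    theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.greedy_trace <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object)[c("k", "accuracy", "auc")],
                              c("accuracy", "auc"),
                              names_to = "metric", values_to = "value")
  ggplot(long, aes(x = .data$k, y = .data$value, colour = .data$metric)) +
    geom_line() + geom_point() +
    labs(x = "Panel size", y = NULL, colour = NULL,
         title = "Greedy search: LOOCV accuracy and in-sample AUC") +
    theme_minimal()
}

#' Index distribution by group (bee-swarm style)
#'
#' Jittered per-sample index values split by case status (and control
#' source for the controls), with the classification cutoff marked.
#'
#' @param report a `validation_report`, or a tibble with columns
#'   `index`, `group`, `control_source`.
#' @param cutoff classification cutoff to mark (default 0).
#' @return a ggplot object.
#' @export
plot_index_distribution <- function(report, cutoff = 0) {
  d <- if (inherits(report, "validation_report")) report$samples else report
  d$panel_group <- ifelse(d$group == "case", "case",
                          paste0("control ", d$control_source))
  ggplot(d, aes(x = .data$panel_group, y = .data$index, colour = .data$group)) +
    geom_jitter(width = 0.25, alpha = 0.5, size = 0.8) +
    geom_hline(yintercept = cutoff, linetype = "dashed") +
    labs(x = NULL, y = "Diagnostic index", colour = NULL) +
    theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.validation_report <- function(object, ...) {
  plot_index_distribution(object, cutoff = object$model$cutoff)
}
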