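#' Plot group accuracy by prototype distance
#'
#' Mean accuracy (with standard-error bars) by folded prototype distance,
#' item type and phase: the typicality gradient and the old-item advantage
#' at distance 2.
#'
#' @param acc_summary A tibble from [group_accuracy()].
#' @return A ggplot object.
#' @export
plot_accuracy <- function(acc_summary) {
  ggplot2::ggplot(acc_summary,
                  ggplot2::aes(x = .data$distance, y = .data$mean_accuracy,
                               colour = .data$item_type,
                               group = .data$item_type)) +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$mean_accuracy - .data$se,
      ymax = .data$mean_accuracy + .data$se)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(ggplot2::vars(.data$phase)) +
    ggplot2::labs(x = "distance from nearer prototype", y = "accuracy",
                  colour = NULL) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Scatter of exemplar vs prototype model fits
#'
#' One point per subject-phase; the identity line separates subjects better
#' fit by the prototype model (above) from those better fit by the exemplar
#' model (below), fits being negative log likelihoods.
#'
#' @param fit_table A tibble from [fit_cohort()] (long over `model`).
#' @return A ggplot object.
#' @export
plot_fit_comparison <- function(fit_table) {
  wide <- tidyr::pivot_wider(fit_table[, c("subject", "phase", "model", "nll")],
                             names_from = "model", values_from = "nll")
  ggplot2::ggplot(wide, ggplot2::aes(x = .data$prototype, y = .data$exemplar)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(ggplot2::vars(.data$phase)) +
    ggplot2::labs(x = "prototype model fit (nll)",
                  y = "exemplar model fit (nll)") +
    ggplot2::theme_minimal()
}

#' Plot strategy-classification proportions
#'
#' @param calls A tibble from [classify_cohort()].
#' @return A ggplot object (stacked proportion bars per phase).
#' @export
plot_strategy_calls <- function(calls) {
  ggplot2::ggplot(calls, ggplot2::aes(x = .data$phase, fill = .data$label)) +
    ggplot2::geom_bar(position = "fill") +
    ggplot2::scale_fill_manual(values = c(prototype = "#4477AA",
                                          exemplar = "#CC6677",
                                          similar = "grey70")) +
    ggplot2::labs(y = "proportion of subjects", x = NULL, fill = "strategy") +
    ggplot2::theme_minimal()
}

#' Plot ROI effect sizes per model
#'
#' @param effects A tibble with `roi`, `model` and `effect` columns.
#' @return A ggplot object (grouped bars).
#' @export
plot_roi_effects <- function(effects) {
  ggplot2::ggplot(effects, ggplot2::aes(x = .data$roi, y = .data$effect,
                                        fill = .data$model)) +
    ggplot2::stat_summary(fun = mean, geom = "col",
                          position = ggplot2::position_dodge()) +
    ggplot2::scale_fill_manual(values = c(prototype = "#4477AA",
                                          exemplar = "#CC6677")) +
    ggplot2::labs(y = "normalized beta (mean/SD)", x = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.design_matrix <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object), -"time",
                              names_to = "regressor")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$regressor), scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = NULL) +
    ggplot2::theme_minimal()
}
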