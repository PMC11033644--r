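#' Bar chart of body-region mention frequencies
#'
#' @param freq Output of [region_frequency()].
#' @return A ggplot object.
#' @export
plot_region_frequency <- function(freq) {
  freq |>
    mutate(region = stats::reorder(.data$region, .data$percent)) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$percent, y = .data$region)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~group) +
    ggplot2::labs(x = "% of mapped anatomy mentions", y = NULL,
                  title = "Body regions mentioned with pain") +
    ggplot2::theme_minimal()
}

#' Forest plot of odds ratios across models
#'
#' @param model_table Output of [run_models()] (or any tibble with `model`,
#'   `term`, `or`, `ci_low`, `ci_high`).
#' @return A ggplot object.
#' @export
plot_odds_ratios <- function(model_table) {
  model_table |>
    ggplot2::ggplot(ggplot2::aes(x = .data$or, y = .data$term,
                                 colour = .data$model)) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$ci_low,
                                          xmax = .data$ci_high),
                             position = ggplot2::position_dodge(width = 0.6)) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Odds ratio (log scale)", y = NULL,
                  title = "Associations with recorded pain") +
    ggplot2::theme_minimal()
}

#' @rdname plot_odds_ratios
#' @param object A `pain_model_table`.
#' @param ... Unused.
#' @importFrom ggplot2 autoplot
#' @export
autoplot.pain_model_table <- function(object, ...) {
  plot_odds_ratios(object)
}
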