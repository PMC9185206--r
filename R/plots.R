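## Report figures: absolute-error bars per formula, within-threshold rates,
## and prediction error against axial length.

#' Plot mean absolute error by formula
#' @param errors a [prediction_errors()] table
#' @return a ggplot object
#' @export
plot_mae_by_formula <- function(errors) {
  s <- summarize_errors(errors)
  ggplot2::ggplot(s, ggplot2::aes(x = .data$formula_id, y = .data$mean_ae)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean_ae - .data$sd_ae,
                                        ymax = .data$mean_ae + .data$sd_ae),
                           width = 0.2) +
    ggplot2::labs(x = NULL, y = "Mean absolute prediction error (D)") +
    ggplot2::theme_minimal()
}

#' Plot prediction error against axial length
#' @param errors a [prediction_errors()] table
#' @return a ggplot object
#' @export
plot_pe_by_al <- function(errors) {
  ggplot2::ggplot(errors, ggplot2::aes(x = .data$al, y = .data$pe,
                                       colour = .data$formula_id)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_smooth(se = FALSE, method = "loess", formula = y ~ x) +
    ggplot2::labs(x = "Axial length (mm)", y = "Prediction error (D)",
                  colour = "Formula") +
    ggplot2::theme_minimal()
}

#' Plot within-threshold percentages
#' @param errors a [prediction_errors()] table
#' @return a ggplot object
#' @export
plot_within_thresholds <- function(errors) {
  s <- summarize_errors(errors)
  long <- data.frame(
    formula_id = rep(s$formula_id, 3),
    threshold = rep(c("0.25 D", "0.50 D", "1.00 D"), each = nrow(s)),
    pct = c(s$pct_within_025, s$pct_within_050, s$pct_within_100))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$formula_id, y = .data$pct,
                                     fill = .data$threshold)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "Eyes within predicted refraction (%)",
                  fill = "Threshold") +
    ggplot2::theme_minimal()
}
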