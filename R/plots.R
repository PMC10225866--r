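#' Plot estimates against true richness with rolling s.d. bounds
#'
#' Scatter of estimates versus truth for selected estimator columns of
#' an ensemble, with rolling-window mean lines and one-s.d. ribbons
#' ([rolling_bounds()]) and the 1:1 reference line.
#'
#' @param ensemble tibble from [run_scenario()].
#' @param estimators estimator columns to show.
#' @param window rolling-window width (default 10).
#' @return a ggplot object.
#' @export
plot_ensemble <- function(ensemble, estimators = c("observed", "chao1",
                                                   "omega"),
                          window = 10) {
  long <- tidyr::pivot_longer(
    ensemble[, c("true_richness", estimators)],
    dplyr::all_of(estimators), names_to = "method",
    values_to = "estimate")
  bounds <- dplyr::bind_rows(lapply(estimators, function(m) {
    b <- rolling_bounds(ensemble$true_richness, ensemble[[m]], window)
    b$method <- m
    b
  }))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$true_richness,
                                     colour = .data$method)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$estimate),
                        alpha = 0.15, size = 0.5) +
    ggplot2::geom_ribbon(
      data = bounds,
      ggplot2::aes(ymin = .data$mean - .data$sd,
                   ymax = .data$mean + .data$sd, fill = .data$method),
      alpha = 0.2, colour = NA) +
    ggplot2::geom_line(data = bounds, ggplot2::aes(y = .data$mean)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::labs(x = "true richness", y = "estimated richness")
}

#' Heatmap of standardized estimator scores
#'
#' @param scores tibble from [standardized_scores()].
#' @return a ggplot object.
#' @export
plot_scores <- function(scores) {
  long <- tidyr::pivot_longer(scores, -"method", names_to = "measure",
                              values_to = "score")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$measure, y = .data$method,
                                     fill = .data$score)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "darkred", mid = "white",
                                  high = "darkblue", midpoint = 0) +
    ggplot2::labs(x = NULL, y = NULL, fill = "score") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
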