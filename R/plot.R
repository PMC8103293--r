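# Summary figures: mean score bar charts for the two analysis grids.

#' Mean accuracy and F1 per classifier and game
#'
#' Bar chart of the mean fold scores of an analysis-one grid, one panel per
#' metric, bars grouped by classifier and filled by game.
#'
#' @param grid A `run_grid` from [run_analysis_one()].
#' @param metrics Metrics to show.
#' @return A ggplot object.
#' @export
plot_performance <- function(grid, metrics = c("accuracy", "f1")) {
  df <- tidyr::pivot_longer(
    tibble::as_tibble(grid)[, c("game", "classifier", metrics)],
    dplyr::all_of(metrics), names_to = "metric", values_to = "score"
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$classifier, y = .data$score,
                                   fill = .data$game)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~metric) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "mean fold score", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Mean scores per level subset and feature family
#'
#' Bar chart of an analysis-two grid: level subsets on the x axis, bars
#' filled by feature family, one panel per metric.
#'
#' @param grid A `run_grid` from [run_analysis_two()].
#' @param metrics Metrics to show.
#' @return A ggplot object.
#' @export
plot_level_grid <- function(grid, metrics = c("accuracy", "f1")) {
  df <- tidyr::pivot_longer(
    tibble::as_tibble(grid)[, c("levels", "family", metrics)],
    dplyr::all_of(metrics), names_to = "metric", values_to = "score"
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$levels, y = .data$score,
                                   fill = .data$family)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~metric) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "level subset", y = "mean fold score", fill = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @exportS3Method ggplot2::autoplot
autoplot.run_grid <- function(object, ...) {
  if (length(unique(object$classifier)) > 1) plot_performance(object, ...)
  else plot_level_grid(object, ...)
}

#' @importFrom rlang .data
NULL
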