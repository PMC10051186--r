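#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Boxplot-style summary of exposure by environment
#'
#' Renders [environment_stats()] the way the campaign figures draw them:
#' whiskers from p10 to p90, box from p25 to p75, median as the central
#' line, and the mean as a black circle.
#'
#' @param object A `wx_env_stats` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.wx_env_stats <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$environment)) +
    ggplot2::geom_boxplot(
      ggplot2::aes(ymin = .data$p10, lower = .data$p25, middle = .data$p50,
                   upper = .data$p75, ymax = .data$p90),
      stat = "identity", width = 0.55, fill = "grey85"
    ) +
    ggplot2::geom_point(ggplot2::aes(y = .data$mean), shape = 16, size = 2) +
    ggplot2::labs(x = NULL, y = object$channel[1],
                  title = "Exposure by microenvironment") +
    ggplot2::theme_minimal()
}

#' Time budget bar chart
#'
#' @param budget Output of [time_budget()].
#' @return A ggplot object.
#' @export
plot_time_budget <- function(budget) {
  ggplot2::ggplot(budget,
                  ggplot2::aes(x = stats::reorder(.data$environment, -.data$fraction),
                               y = .data$fraction)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::scale_y_continuous(labels = function(x) sprintf("%.0f%%", 100 * x)) +
    ggplot2::labs(x = NULL, y = "share of labelled time",
                  title = "Time budget over microenvironments") +
    ggplot2::theme_minimal()
}

#' Metric profile of a sensor evaluation
#'
#' @param object A `wx_sensor_eval`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.wx_sensor_eval <- function(object, ...) {
  df <- tidy(object) %>% filter(.data$metric != "rmse", !is.na(.data$value))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = object$ipi, linetype = 2) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "score",
                  title = sprintf("Sensor metrics (IPI = %.2f)", object$ipi)) +
    ggplot2::theme_minimal()
}

#' Confusion heatmap of an environment evaluation
#'
#' @param object A `wx_evaluation`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.wx_evaluation <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$truth,
                                   fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), colour = "white") +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(title = sprintf("Confusion matrix (accuracy %.3f)",
                                  object$accuracy)) +
    ggplot2::theme_minimal()
}
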