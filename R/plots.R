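#' Plot a per-year metrics series
#'
#' @param object A `metrics_series` (from [run_conventional()] /
#'   [run_two_part()]).
#' @param metrics Which metrics to show.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.metrics_series <- function(object, metrics = c("gain", "genic_sd"), ...) {
  df <- object[object$metric %in% metrics, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$year, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(ggplot2::vars(.data$metric), scales = "free_y") +
    ggplot2::labs(x = "year", y = NULL)
}

#' Plot aggregated scenario trajectories with confidence ribbons
#'
#' @param object A `metrics_summary` (from [summarize_replicates()]).
#' @param metrics Which metrics to show.
#' @param ... Unused.
#' @export
autoplot.metrics_summary <- function(object, metrics = c("gain", "genic_sd"), ...) {
  df <- object[object$metric %in% metrics, ]
  has_scenario <- "scenario" %in% names(df)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$year, y = .data$mean))
  if (has_scenario) {
    p <- p + ggplot2::aes(colour = .data$scenario, fill = .data$scenario)
  }
  p +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(ggplot2::vars(.data$metric), scales = "free_y") +
    ggplot2::labs(x = "year", y = NULL)
}

#' Plot a gain-coancestry frontier
#'
#' @param object An `ocs_frontier` (from [ocs_frontier()]).
#' @param ... Unused.
#' @export
autoplot.ocs_frontier <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$group_coancestry, y = .data$gain)) +
    ggplot2::geom_path() +
    ggplot2::geom_point() +
    ggplot2::geom_text(ggplot2::aes(label = .data$degrees),
                       vjust = -0.6, size = 3) +
    ggplot2::labs(x = "group coancestry", y = "expected gain",
                  title = "gain-coancestry frontier by penalty degrees")
}

#' Plot the gain-diversity trajectory behind an efficiency estimate
#'
#' @param object An `efficiency_estimate`.
#' @param ... Unused.
#' @export
autoplot.efficiency_estimate <- function(object, ...) {
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$diversity_loss, y = .data$gain)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(intercept = object$intercept, slope = object$slope) +
    ggplot2::labs(x = "lost genetic diversity (1 - relative genic SD)",
                  y = "standardized genetic gain",
                  subtitle = sprintf("efficiency (robust slope) = %.1f",
                                     object$slope))
}

#' Plot the genic-variance decay behind an Ne estimate
#'
#' @param object An `ne_estimate`.
#' @param ... Unused.
#' @export
autoplot.ne_estimate <- function(object, ...) {
  df <- object$data
  df$fitted <- stats::fitted(object$fit)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$year)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$genic_variance)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), linetype = 2) +
    ggplot2::labs(y = "genic variance",
                  subtitle = if (is.na(object$Ne)) "Ne undefined (no decay)"
                  else sprintf("delta_C = %.4g, Ne = %.1f",
                               object$delta_C, object$Ne))
}
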