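#' Plot an engagement timeline
#'
#' Step plot of the engagement level over session time, one panel per
#' participant-session, with the weighted engagement score overlaid.
#'
#' @param object An `engagement_timeline` from [build_timeline()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.engagement_timeline <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t / 60)) +
    ggplot2::geom_step(ggplot2::aes(y = .data$level), color = "grey30") +
    ggplot2::geom_line(
      ggplot2::aes(y = 4 * .data$weighted_score),
      color = "steelblue", alpha = 0.6
    ) +
    ggplot2::facet_wrap(~ session_id + participant_id) +
    ggplot2::scale_y_continuous(
      "engagement level",
      breaks = 0:4,
      sec.axis = ggplot2::sec_axis(~ . / 4, name = "weighted score")
    ) +
    ggplot2::labs(x = "session time (min)") +
    ggplot2::theme_minimal()
}

#' Plot path-model estimates
#'
#' Dot-and-whisker plot of the standardized path estimates with approximate
#' 95% intervals from the unstandardized SEs scaled to the standardized
#' metric.
#'
#' @param object A `path_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.path_fit <- function(object, ...) {
  df <- object$edges %>%
    mutate(
      path = paste(.data$from, "→", .data$to),
      scale = if_else(.data$estimate == 0, 1, .data$std_estimate / .data$estimate),
      lo = .data$std_estimate - 1.96 * .data$se * abs(.data$scale),
      hi = .data$std_estimate + 1.96 * .data$se * abs(.data$scale)
    )
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$std_estimate,
    y = stats::reorder(.data$path, .data$std_estimate)
  )) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, color = "grey60") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$lo, xmax = .data$hi),
      height = 0.2, color = "grey40"
    ) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "standardized estimate", y = NULL) +
    ggplot2::theme_minimal()
}
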