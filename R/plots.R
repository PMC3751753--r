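# ggplot2 views of the result objects.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot truth against cross-validated prediction
#'
#' @param object a `capacity_eval` from [loso_cv()].
#' @param ... unused.
#' @return a ggplot: expert rating vs leave-one-session-out prediction,
#'   one point per task instance, identity line for reference.
#' @method autoplot capacity_eval
#' @export
autoplot.capacity_eval <- function(object, ...) {
  df <- object$predictions
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$truth, y = .data$prediction, colour = .data$subject_id
  )) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
      colour = "grey50"
    ) +
    ggplot2::geom_point(size = 2) +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(
      title = sprintf("Capacity estimation: %s", object$task_class),
      subtitle = sprintf(
        "LOSO RMSE = %.3f, r = %.2f", object$metrics$rmse,
        object$metrics$r
      ),
      x = "expert rating (normalized)", y = "estimated rating",
      colour = "subject"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a session's magnitude traces
#'
#' @param session a `session_recording`.
#' @param channel `"accel"` or `"gyro"`.
#' @return a ggplot of the magnitude series faceted by placement, with
#'   task segments shaded.
#' @export
plot_session <- function(session, channel = c("accel", "gyro")) {
  channel <- match.arg(channel)
  df <- purrr::map(names(session$traces), function(p) {
    tibble::tibble(
      placement = p,
      time_s = session$traces[[p]]$time_s,
      mag = magnitude(session$traces[[p]], channel)
    )
  }) |> dplyr::bind_rows()
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$time_s, .data$mag)) +
    ggplot2::geom_line(linewidth = 0.2) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$placement),
      scales = "free_y"
    ) +
    ggplot2::labs(
      x = "time (s)",
      y = if (channel == "accel") "|a| (g)" else "|omega| (deg/s)"
    ) +
    ggplot2::theme_minimal()
  if (!is.null(session$segments)) {
    p <- p + ggplot2::geom_rect(
      data = session$segments,
      ggplot2::aes(
        xmin = .data$start_s, xmax = .data$end_s,
        ymin = -Inf, ymax = Inf
      ),
      inherit.aes = FALSE, alpha = 0.12, fill = "steelblue"
    )
  }
  p
}

#' Scatter of the pooled task-independent features
#'
#' One point per (subject, week): mean smoothness against mean
#' angular-velocity range, point size for mean rotation energy, coloured
#' by the pooled rating — the feature-space view in which recovering
#' subjects drift toward high-smoothness, high-range, high-energy corner.
#'
#' @param pooled output of [pooled_generalization()].
#' @return a ggplot.
#' @export
plot_pooled_features <- function(pooled) {
  ggplot2::ggplot(pooled, ggplot2::aes(
    x = .data$RANG, y = .data$SM, size = .data$ARE, colour = .data$rating
  )) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::scale_colour_viridis_c() +
    ggplot2::labs(
      x = "mean RANG (deg/s)", y = "mean SM",
      size = expression("mean ARE " * (deg / s)^2), colour = "pooled rating"
    ) +
    ggplot2::theme_minimal()
}
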