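#' Diagnostic plots for a gait analysis
#'
#' `plot_gait_events()` shows the gyroscope-magnitude and pitch traces with
#' the detected heel-strike / toe-off events and foot-flat shading;
#' `plot_gait_path()` the estimated 2D (horizontal-plane) foot path;
#' `plot_stride_histogram()` the histogram of kept stride lengths.
#' `autoplot()` dispatches between them.
#'
#' @param x A `gait_analysis` from [analyze_gait()].
#' @return A ggplot object.
#' @export
plot_gait_events <- function(x) {
  stopifnot(inherits(x, "gait_analysis"))
  df <- tibble::tibble(
    time = x$recording$time,
    `gyro magnitude [rad/s]` = x$recording$gyr_mag,
    `pitch [deg]` = x$orientation$pitch
  ) |>
    tidyr::pivot_longer(-"time", names_to = "signal", values_to = "value")
  ff <- x$zones$foot_flat_intervals
  ev <- dplyr::bind_rows(
    tibble::tibble(time = x$events$t_hs, event = "heel-strike",
                   value = x$orientation$pitch[x$events$i_hs],
                   signal = "pitch [deg]"),
    tibble::tibble(time = x$events$t_to, event = "toe-off",
                   value = x$orientation$pitch[x$events$i_to],
                   signal = "pitch [deg]")
  )
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$value))
  if (nrow(ff) > 0L) {
    p <- p + ggplot2::geom_rect(
      data = ff,
      ggplot2::aes(xmin = .data$t_start, xmax = .data$t_end,
                   ymin = -Inf, ymax = Inf),
      inherit.aes = FALSE, fill = "grey85"
    )
  }
  p +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::geom_point(data = ev,
                        ggplot2::aes(colour = .data$event), size = 1.5) +
    ggplot2::facet_wrap(~signal, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time [s]", y = NULL, colour = NULL,
                  title = "Gait events over gyroscope magnitude and pitch",
                  subtitle = "shaded: foot-flat intervals") +
    ggplot2::theme_minimal()
}

#' @rdname plot_gait_events
#' @export
plot_gait_path <- function(x) {
  stopifnot(inherits(x, "gait_analysis"))
  ggplot2::ggplot(x$trajectory, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_path(linewidth = 0.3) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x [m]", y = "y [m]",
                  title = "Estimated 2D foot path") +
    ggplot2::theme_minimal()
}

#' @rdname plot_gait_events
#' @param binwidth Histogram bin width in metres.
#' @export
plot_stride_histogram <- function(x, binwidth = 0.05) {
  stopifnot(inherits(x, "gait_analysis"))
  ggplot2::ggplot(x$strides, ggplot2::aes(.data$stride_length)) +
    ggplot2::geom_histogram(binwidth = binwidth, fill = "steelblue",
                            colour = "white") +
    ggplot2::labs(x = "stride length [m]", y = "strides",
                  title = "Stride-length distribution (kept strides)") +
    ggplot2::theme_minimal()
}

#' @rdname plot_gait_events
#' @param object A `gait_analysis`.
#' @param type Which diagnostic: `"events"`, `"path"` or `"histogram"`.
#' @param ... Passed on to the underlying `plot_*` function.
#' @importFrom ggplot2 autoplot
#' @method autoplot gait_analysis
#' @export
autoplot.gait_analysis <- function(object,
                                   type = c("events", "path", "histogram"),
                                   ...) {
  switch(match.arg(type),
         events = plot_gait_events(object),
         path = plot_gait_path(object),
         histogram = plot_stride_histogram(object, ...))
}
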