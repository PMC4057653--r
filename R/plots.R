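# ggplot2 displays for the result types.

#' Plot a pupil trace
#'
#' Major and minor axis lengths over time; interpolated (blink-repaired)
#' samples, if present, are marked.
#'
#' @param object A `pupil_trace`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pupil_trace <- function(object, ...) {
  acols <- axis_cols(object)
  unit <- trace_units(object)
  df <- as_tibble(object) |>
    tidyr::pivot_longer(dplyr::all_of(acols), names_to = "axis",
                        values_to = "length")
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$timestamp_s, .data$length,
                                        color = .data$axis)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time [s]", y = sprintf("axis length [%s]", unit),
                  color = NULL, title = sprintf("pupil trace (%s eye)",
                                                df$eye[1] %||% "?"))
  if ("interpolated" %in% names(df) && any(df$interpolated)) {
    p <- p + ggplot2::geom_point(data = df[df$interpolated, ], shape = 1)
  }
  p
}

#' Plot a stimulus waveform
#'
#' @param object A `stimulus_waveform` from [generate_waveform()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.stimulus_waveform <- function(object, ...) {
  pat <- attr(object, "pattern")
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(.data$time_s, .data$luminance)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "time [s]", y = expression("luminance [cd/" * m^2 * "]"),
                  title = sprintf("%s stimulus (%s eye, %s)",
                                  pat$shape, pat$eye, pat$color))
}

#' Plot a validation report
#'
#' Per-phantom accuracy and repeatability with the protocol bounds.
#'
#' @param object A `validation_report` from [validate_system()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.validation_report <- function(object, ...) {
  df <- as_tibble(object) |>
    tidyr::pivot_longer(c("max_accuracy_percent", "max_repeatability_percent"),
                        names_to = "metric", values_to = "percent") |>
    dplyr::mutate(metric = ifelse(.data$metric == "max_accuracy_percent",
                                  "accuracy", "repeatability"))
  bounds <- tibble(metric = c("accuracy", "repeatability"), bound = c(0.5, 4))
  ggplot2::ggplot(df, ggplot2::aes(factor(.data$true_major_px), .data$percent)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(data = bounds, ggplot2::aes(yintercept = .data$bound),
                        linetype = 2) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "phantom size [px]", y = "[%]",
                  title = "validation protocol")
}

#' Display a frame as an image
#'
#' @param frame A [raw_frame()] or matrix.
#' @param ... Unused.
#' @return A ggplot raster of the frame.
#' @export
plot_frame <- function(frame, ...) {
  m <- frame_pixels(frame)
  df <- tibble(
    x = rep(seq_len(ncol(m)) - 0.5, each = nrow(m)),
    y = rep(seq_len(nrow(m)) - 0.5, times = ncol(m)),
    intensity = as.vector(m)
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 limits = c(0, 255)) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x [px]", y = "y [px]")
}
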