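# ggplot2 views of the main result types.

#' @importFrom ggplot2 autoplot ggplot aes geom_tile geom_raster geom_point
#'   geom_path geom_line geom_segment scale_y_reverse coord_equal labs
#'   scale_fill_identity scale_fill_viridis_c theme_minimal
NULL

#' @export
ggplot2::autoplot

#' Plot a grid scan as its dominant-colour mosaic
#'
#' @param object A [grid_scan()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.grid_scan <- function(object, ...) {
  df <- mutate(as_tibble(object),
    fill = grDevices::rgb(.data$r, .data$g, .data$b, maxColorValue = 255)
  )
  ggplot(df, aes(x = .data$col, y = .data$row, fill = .data$fill)) +
    geom_tile(colour = "grey30", linewidth = 0.2) +
    scale_fill_identity() +
    scale_y_reverse() +
    coord_equal() +
    labs(x = "column", y = "row", title = "Dominant colour per grid cell") +
    theme_minimal()
}

#' Plot a gaze heatmap
#'
#' @param object A [gaze_heatmap()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.gaze_heatmap <- function(object, ...) {
  ggplot(as_tibble(object), aes(x = .data$x, y = .data$y, fill = .data$intensity)) +
    geom_raster() +
    scale_fill_viridis_c(name = "intensity") +
    scale_y_reverse() +
    coord_equal() +
    labs(x = "x (px)", y = "y (px)", title = "Duration-weighted gaze heatmap") +
    theme_minimal()
}

#' Plot a fixation scanpath
#'
#' Fixations as points sized by duration, connected in time order.
#'
#' @param fixations Fixation tibble from [detect_fixations()].
#' @param width,height Display extent for the axes.
#' @return A ggplot.
#' @export
plot_scanpath <- function(fixations, width = 1920, height = 1080) {
  check_columns(fixations, c("cx", "cy", "onset", "duration"), "fixations")
  df <- arrange(as_tibble(fixations), .data$onset)
  ggplot(df, aes(x = .data$cx, y = .data$cy)) +
    geom_path(colour = "grey50") +
    geom_point(aes(size = .data$duration), alpha = 0.7, colour = "#2166ac") +
    ggplot2::xlim(0, width) +
    scale_y_reverse(limits = c(height, 0)) +
    coord_equal() +
    labs(x = "x (px)", y = "y (px)", size = "duration (ms)",
         title = "Fixation scanpath") +
    theme_minimal()
}

#' Plot a melody as a piano roll
#'
#' @param events Event tibble (`pitch`, `duration`, `velocity`, `offset`).
#' @return A ggplot.
#' @export
plot_piano_roll <- function(events) {
  check_events(events)
  df <- mutate(as_tibble(events),
    onset = cumsum(.data$offset),
    end = .data$onset + .data$duration
  )
  ggplot(df) +
    geom_segment(
      aes(x = .data$onset, xend = .data$end, y = .data$pitch,
          yend = .data$pitch, colour = .data$velocity),
      linewidth = 3
    ) +
    scale_fill_viridis_c() +
    labs(x = "time (sixteenth-note units)", y = "MIDI pitch",
         colour = "velocity", title = "Piano roll") +
    theme_minimal()
}

#' Plot the training loss trace
#'
#' @param object A `melody_model`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.melody_model <- function(object, ...) {
  ggplot(tidy(object), aes(x = .data$epoch, y = .data$loss)) +
    geom_line() +
    geom_point() +
    labs(x = "epoch", y = "mean training loss", title = "Melody model training") +
    theme_minimal()
}
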