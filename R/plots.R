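#' Arrow-map plot of a velocity field
#'
#' Arrows at window centers, drawn at `display_scale` times the actual
#' displacement, coloured by radial velocity (blue inward, red outward) when
#' the field has been radially projected. The y axis is reversed to match
#' the raster convention.
#'
#' @param object A `velocity_field` (ideally after [radial_project()]).
#' @param display_scale Arrow magnification.
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot velocity_field
#' @export
autoplot.velocity_field <- function(object, display_scale = 2, ...) {
  am <- arrow_map(object, display_scale)
  p <- ggplot2::ggplot(am, ggplot2::aes(x = .data$x, y = .data$y,
                                        xend = .data$xend, yend = .data$yend))
  if (any(is.finite(am$radial_um_s))) {
    p <- p + ggplot2::geom_segment(
      ggplot2::aes(colour = .data$radial_um_s),
      arrow = ggplot2::arrow(length = ggplot2::unit(1.5, "mm"))) +
      ggplot2::scale_colour_gradient2(low = "#2166AC", mid = "grey85",
                                      high = "#B2182B", midpoint = 0,
                                      name = "radial\n(um/s)")
  } else {
    p <- p + ggplot2::geom_segment(
      arrow = ggplot2::arrow(length = ggplot2::unit(1.5, "mm")))
  }
  p + ggplot2::scale_y_reverse() + ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (px)", y = "y (px)") + ggplot2::theme_minimal()
}

#' Recovery-curve plot
#'
#' @param object A `recovery_curve`.
#' @param fraction Reference fraction drawn as a dashed line.
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot recovery_curve
#' @export
autoplot.recovery_curve <- function(object, fraction = 0.9, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$time_s, y = .data$ratio)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_hline(yintercept = fraction, linetype = "dashed") +
    ggplot2::labs(x = "time since conversion (s)",
                  y = "relative intensity (converted / unconverted)") +
    ggplot2::theme_minimal()
}

#' Radial-displacement heat map as a ggplot tile grid
#'
#' Kymograph-style view of [heatmap_accumulate()] output: diverging colour
#' scale centred at zero radial displacement.
#'
#' @param accum Output of [heatmap_accumulate()].
#' @param value Column to map to fill.
#' @return A ggplot object.
#' @export
plot_radial_heatmap <- function(accum, value = "total_um") {
  ggplot2::ggplot(accum, ggplot2::aes(x = .data$x, y = .data$y,
                                      fill = .data[[value]])) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "white",
                                  high = "#B2182B", midpoint = 0,
                                  na.value = "grey70", name = value) +
    ggplot2::scale_y_reverse() + ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (px)", y = "y (px)") + ggplot2::theme_minimal()
}

#' Binned mean radial velocity plot
#'
#' @param binned Output of [mean_radial_series()].
#' @return A ggplot object.
#' @export
plot_radial_series <- function(binned) {
  ggplot2::ggplot(binned, ggplot2::aes(x = .data$t_mid_s,
                                       y = .data$mean_radial_um_s)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_col(width = diff(binned$t_start_s[1:2]) * 0.9,
                      fill = "grey30") +
    ggplot2::labs(x = "time (s)", y = "mean radial velocity (um/s)") +
    ggplot2::theme_minimal()
}

#' Line-profile plot
#'
#' @param profile Output of [line_profile()].
#' @return A ggplot object.
#' @export
plot_line_profile <- function(profile) {
  ggplot2::ggplot(profile, ggplot2::aes(x = .data$arclength_um,
                                        y = .data$intensity)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "arclength (um)", y = "mean intensity") +
    ggplot2::theme_minimal()
}
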