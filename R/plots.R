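# ggplot2 views of the main result types.

#' Normalised biovolume time courses
#'
#' One line per position: normalised (or raw) total biovolume against
#' experiment time, the view in which growth, peak and dispersal are read.
#'
#' @param series Tibble from [normalize_series()] (or [quantify_series()]).
#' @return A ggplot.
#' @export
plot_biovolume <- function(series) {
  has_norm <- "vnorm" %in% names(series)
  y <- if (has_norm) "vnorm" else "biovolume_um3"
  ggplot2::ggplot(series, ggplot2::aes(x = .data$t_min, y = .data[[y]],
                                       colour = .data$position)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (min)",
                  y = if (has_norm) expression(V[norm]) else
                    expression(V ~ (mu * m^3)))
}

#' Bubble plot of cluster positions and sizes
#'
#' Each cluster is drawn at its centroid with a bubble sized by its
#' equivalent sphere diameter.
#'
#' @param clusters Cluster tibble for one cycle.
#' @return A ggplot.
#' @export
plot_bubbles <- function(clusters) {
  ggplot2::ggplot(bubble_data(clusters),
                  ggplot2::aes(x = .data$x_um, y = .data$y_um,
                               size = .data$d_um)) +
    ggplot2::geom_point(alpha = 0.6, colour = "darkgreen") +
    ggplot2::scale_size_area(name = expression(D ~ (mu * m))) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = expression(x ~ (mu * m)), y = expression(y ~ (mu * m)))
}

#' Dispersal onset along the channel
#'
#' Mean onset time (+- SD over replicate areas) against axial position;
#' downstream-first dispersal shows as onset decreasing towards position 12.
#'
#' @param by_location Tibble from [summarize_by_location()].
#' @return A ggplot.
#' @export
plot_dispersal <- function(by_location) {
  ggplot2::ggplot(by_location, ggplot2::aes(x = .data$x_index,
                                            y = .data$t_disp_mean)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$t_disp_mean - dplyr::coalesce(.data$t_disp_sd, 0),
      ymax = .data$t_disp_mean + dplyr::coalesce(.data$t_disp_sd, 0))) +
    ggplot2::scale_x_continuous(breaks = by_location$x_index) +
    ggplot2::labs(x = "axial position (12 = outlet)",
                  y = expression(bar(t)[disp] ~ (min)))
}

#' @export
autoplot.growth_fit <- function(object, ...) {
  dat <- object$data |> dplyr::filter(.data$biovolume_um3 > 0)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$t_min,
                                    y = .data$biovolume_um3)) +
    ggplot2::geom_point(ggplot2::aes(shape = .data$used)) +
    ggplot2::geom_function(
      fun = function(t) object$v0 * exp(object$g * t), colour = "red") +
    ggplot2::scale_y_log10() +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 16, `FALSE` = 1),
                                name = "in fit") +
    ggplot2::labs(x = "time (min)", y = expression(V ~ (mu * m^3)))
}
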