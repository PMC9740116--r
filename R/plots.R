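# ggplot2 views of meshes, scalar series and scenario deltas.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an outflow mesh coloured by region
#'
#' @param object An [outflow_mesh].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.outflow_mesh <- function(object, ...) {
  tri <- object$triangles
  df <- tibble(
    id = rep(seq_len(nrow(tri)), each = 3L),
    region = rep(object$region, each = 3L),
    x = object$vertices[as.vector(t(tri)), 1L],
    y = object$vertices[as.vector(t(tri)), 2L]
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, group = .data$id,
                                   fill = .data$region)) +
    ggplot2::geom_polygon(colour = NA) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)", fill = "region")
}

#' Plot the scalar time series of a scenario run
#'
#' @param object An `efsi_results`.
#' @param quantities Series columns to show.
#' @param ... Unused.
#' @return A ggplot faceted by quantity.
#' @export
autoplot.efsi_results <- function(object,
                                  quantities = c("max_velocity_mm_s",
                                                 "max_pressure_mmhg",
                                                 "tm_displacement_um"), ...) {
  df <- tidy.efsi_results(object) %>% filter(.data$quantity %in% quantities)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~quantity, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = NULL, title = object$config$name)
}

#' Plot a scenario delta report
#'
#' @param object A `delta_report`.
#' @param ... Unused.
#' @return A ggplot of the per-step deltas faceted by quantity.
#' @export
autoplot.delta_report <- function(object, ...) {
  nm <- attr(object, "names_ab")
  df <- tidyr::pivot_longer(as_tibble(object), -c("step", "time"),
                            names_to = "quantity", values_to = "delta")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$delta)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~quantity, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = "delta (B - A)",
                  title = paste(nm[2L], "minus", nm[1L]))
}

#' Plot streamlines coloured by speed
#'
#' @param lines Tibble from [streamlines()].
#' @return A ggplot.
#' @export
plot_streamlines <- function(lines) {
  ggplot2::ggplot(lines, ggplot2::aes(x = .data$x_um, y = .data$y_um,
                                      group = .data$id,
                                      colour = .data$speed_mm_s)) +
    ggplot2::geom_path() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)", colour = "speed (mm/s)")
}
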