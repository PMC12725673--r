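#' Plot a decadal VCC aggregate
#'
#' Mean virtual catch per decade with +/- one standard deviation error
#' bars and the cubic trend line through the means (including the
#' pre-1980s baseline point at 1).
#'
#' @param object a `vcc_aggregate` tibble from [vcc_aggregate()].
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot vcc_aggregate
#' @export
autoplot.vcc_aggregate <- function(object, ...) {
  agg <- tibble::as_tibble(object)
  agg$index <- decade_index(agg$decade)
  fit <- fit_decadal_trend(agg)
  curve <- tibble::tibble(index = seq(0, 4, by = 0.05))
  curve$value <- predict(fit, curve$index)
  ggplot2::ggplot(agg, ggplot2::aes(x = .data$index, y = .data$mean)) +
    ggplot2::geom_line(data = curve,
                       ggplot2::aes(x = .data$index, y = .data$value),
                       linewidth = 0.4) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$sd,
                   ymax = .data$mean + .data$sd),
      width = 0.1) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_x_continuous(
      breaks = 0:4, labels = c("pre-1980s", vcc_decades())) +
    ggplot2::labs(x = NULL, y = "virtual catch (baseline = 1)") +
    ggplot2::theme_minimal()
}

#' Plot a grid surface
#'
#' Raster heat map of an effort or VCC surface; VCC surfaces use a
#' diverging palette centred at zero.
#'
#' @param object a `grid_surface`.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot grid_surface
#' @export
autoplot.grid_surface <- function(object, ...) {
  df <- tibble::as_tibble(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                        fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "longitude", y = "latitude",
                  fill = object$kind) +
    ggplot2::theme_minimal()
  if (object$kind == "vcc") {
    p + ggplot2::scale_fill_gradient2(low = "#b2182b", mid = "#f7f7f7",
                                      high = "#2166ac", midpoint = 0)
  } else {
    p + ggplot2::scale_fill_viridis_c()
  }
}

#' Plot a driver ranking
#'
#' Horizontal bar chart of how many fishers cite each perceived decline
#' driver, most cited at the top.
#'
#' @param drivers tibble from [driver_frequency()].
#' @return A ggplot object.
#' @export
plot_driver_ranking <- function(drivers) {
  drivers$driver <- factor(drivers$driver, levels = rev(drivers$driver))
  ggplot2::ggplot(drivers, ggplot2::aes(x = .data$n, y = .data$driver)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "fishers citing driver", y = NULL) +
    ggplot2::theme_minimal()
}
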