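# ggplot2 display helpers.

#' Plot a localization or subunit table
#'
#' x-y scatter colored by z elevation, the standard first look at a 3D
#' MINFLUX dataset.
#'
#' @param table Tibble with `x, y, z` columns (nm).
#' @param point_size Point size passed to [ggplot2::geom_point()].
#' @return A ggplot object.
#' @export
plot_localizations <- function(table, point_size = 0.5) {
  ggplot2::ggplot(table, ggplot2::aes(x = .data$x, y = .data$y, colour = .data$z)) +
    ggplot2::geom_point(size = point_size) +
    ggplot2::coord_equal() +
    ggplot2::scale_colour_viridis_c(name = "z (nm)") +
    ggplot2::labs(x = "x (nm)", y = "y (nm)")
}

#' @describeIn estimate_labeling_efficiency Cumulative labeled-segment
#'   histogram with the fitted model curve and reference curves at nearby
#'   efficiencies.
#' @param object A `ple_estimate`.
#' @param reference_p Efficiencies of the reference curves.
#' @param ... Unused.
#' @export
autoplot.ple_estimate <- function(object, reference_p = c(0.3, 0.5, 0.7, 0.9), ...) {
  obs <- tidy(object) |>
    dplyr::filter(.data$k >= object$kmin) |>
    dplyr::mutate(cum = cumsum(.data$prop_observed))
  curve_tbl <- function(p, label) {
    pred <- predicted_segment_distribution(p, m = object$m, s = object$s,
                                           kmin = object$kmin)
    tibble(k = pred$k, cum = cumsum(pred$prob), p = label)
  }
  refs <- dplyr::bind_rows(lapply(reference_p, function(p)
    curve_tbl(p, sprintf("p = %.0f%%", 100 * p))))
  best <- curve_tbl(object$p_le, "best fit")
  ggplot2::ggplot(obs, ggplot2::aes(x = .data$k, y = .data$cum)) +
    ggplot2::geom_line(data = refs, ggplot2::aes(group = .data$p), colour = "grey70") +
    ggplot2::geom_line(data = best, linetype = "dashed", colour = "black") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      x = "labeled segments per pore (k)",
      y = "cumulative fraction of pores",
      title = sprintf("p_LE = %.1f%% ± %.1f%%", 100 * object$p_le,
                      100 * object$stderr)
    )
}

#' @describeIn compute_cluster_stats Histogram of cluster sizes (subunits per
#'   cluster, log10 x-axis).
#' @param object A `cluster_stats`.
#' @param ... Unused.
#' @export
autoplot.cluster_stats <- function(object, ...) {
  ggplot2::ggplot(object$sizes, ggplot2::aes(x = .data$size_su)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey40") +
    ggplot2::geom_vline(xintercept = object$large_threshold, linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "subunits per cluster", y = "clusters")
}

#' @describeIn render_2d Raster display of a rendered image.
#' @param object A `minflux_image`.
#' @param ... Unused.
#' @export
autoplot.minflux_image <- function(object, ...) {
  px <- attr(object, "pixel_size")
  origin <- attr(object, "origin")
  m <- unclass(object)
  df <- tidyr::expand_grid(row = seq_len(nrow(m)), col = seq_len(ncol(m)))
  df$intensity <- m[cbind(df$row, df$col)]
  df$x <- origin[["x"]] + (df$col - 0.5) * px
  df$y <- origin[["y"]] + (df$row - 0.5) * px
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_viridis_c(name = "intensity") +
    ggplot2::labs(x = "x (nm)", y = "y (nm)")
}
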