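#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

# Colour-blind-safe palette for the eight categories, in standard order.
category_palette <- function() {
  stats::setNames(
    c("#e41a1c", "#ff7f00", "#b2182b", "#7b3294", "#fdae61",
      "#66c2a5", "#3288bd", "#878787", "#f0f0f0"),
    c(eha_categories(), "none"))
}

#' Plot an emerging-hotspot category map
#'
#' @param object an `eha_result`.
#' @param show_none draw the "none" locations (default TRUE, light grey).
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.eha_result <- function(object, show_none = TRUE, ...) {
  df <- object$locations
  if (!show_none) df <- df[df$category != "none", ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$category)) +
    ggplot2::geom_tile(width = object$bin_size, height = object$bin_size) +
    ggplot2::scale_fill_manual(values = category_palette(), drop = TRUE) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (m)", y = "y (m)", fill = "category",
                  title = "Emerging hotspot categories") +
    ggplot2::theme_minimal()
}

#' Plot a Gi* z-score field
#'
#' @param object a `gi_star_field`.
#' @param years subset of year indices to draw (default: first, middle,
#'   last).
#' @param ... unused.
#' @return A ggplot faceted by year.
#' @export
autoplot.gi_star_field <- function(object, years = NULL, ...) {
  Tn <- object$n_years
  years <- years %||% unique(c(1L, ceiling(Tn / 2), Tn))
  df <- tidy.gi_star_field(object)
  df <- df[df$year %in% years, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = -.data$row,
                                   fill = .data$z)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", midpoint = 0) +
    ggplot2::facet_wrap(~year, labeller = ggplot2::label_both) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "bin column", y = "bin row", fill = "Gi* z") +
    ggplot2::theme_minimal()
}

#' Plot an annual loss series
#'
#' @param series tibble from [annual_loss_series()].
#' @param year_base calendar year of code 0 (default 2000).
#' @return A ggplot column chart with the mean annual rate as a reference
#'   line.
#' @export
plot_annual_loss <- function(series, year_base = 2000) {
  mean_rate <- attr(series, "total_km2") / nrow(series)
  ggplot2::ggplot(series, ggplot2::aes(x = .data$year + year_base,
                                       y = .data$area_km2)) +
    ggplot2::geom_col(fill = "#66c2a5") +
    ggplot2::geom_hline(yintercept = mean_rate, linetype = 2) +
    ggplot2::labs(x = "year", y = expression(km^2),
                  title = "Annual forest loss",
                  subtitle = sprintf("mean %.0f km²/yr", mean_rate)) +
    ggplot2::theme_minimal()
}

#' Plot a boundary-distance profile
#'
#' @param profile tibble from [boundary_distance_profile()].
#' @param drop_none drop the "none" class (default TRUE).
#' @return A stacked ggplot column chart of category counts per signed
#'   distance ring (negative = inside a protected area).
#' @export
plot_boundary_profile <- function(profile, drop_none = TRUE) {
  df <- profile
  if (drop_none) df <- df[df$category != "none", ]
  ggplot2::ggplot(df, ggplot2::aes(x = (.data$ring_min + .data$ring_max) / 2,
                                   y = .data$n, fill = .data$category)) +
    ggplot2::geom_col(width = df$ring_max[1] - df$ring_min[1]) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::scale_fill_manual(values = category_palette()) +
    ggplot2::labs(x = "signed distance to PA boundary (m; negative = inside)",
                  y = "locations", fill = "category") +
    ggplot2::theme_minimal()
}
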