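# ggplot2 views of the result types. These are quicklooks on the
# unprojected lat/lon grid, not cartographic products.

#' @export
autoplot.bioclim_trend <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$lon, .data$lat)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$slope)) +
    ggplot2::geom_point(
      data = dplyr::filter(object, .data$significant),
      shape = ".", colour = "black"
    ) +
    ggplot2::scale_fill_gradient2(low = "#2166ac", high = "#b2182b") +
    ggplot2::labs(
      title = sprintf(
        "%s trend, %d-%d", attr(object, "variable"),
        attr(object, "period")[1], attr(object, "period")[2]
      ),
      fill = attr(object, "units"),
      x = "Longitude", y = "Latitude",
      caption = "dots: Mann-Kendall p <= 0.05"
    )
}

#' @export
autoplot.bioclim_anomaly <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    .data$year, .data$smoothed,
    colour = factor(.data$region)
  )) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::labs(
      title = sprintf(
        "%s anomalies vs %d-%d mean (%d-yr smoothing)",
        attr(object, "variable"), attr(object, "baseline")[1],
        attr(object, "baseline")[2], attr(object, "smooth")
      ),
      x = "Year", y = "Anomaly", colour = "Region"
    )
}

#' @export
autoplot.bioclim_area_series <- function(object, ...) {
  rule <- attr(object, "rule")
  ggplot2::ggplot(object, ggplot2::aes(
    .data$year, .data$total_km2,
    colour = factor(.data$region)
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_smooth(
      method = "lm", formula = y ~ x, se = FALSE, linewidth = 0.4
    ) +
    ggplot2::labs(
      title = sprintf(
        "Area with %s %s %s", rule$variable, rule$comparator,
        if (is.matrix(rule$threshold)) "local threshold" else rule$threshold
      ),
      x = "Year", y = expression(Area ~ (km^2)), colour = "Region"
    )
}

#' @export
autoplot.bioclim_synthesis <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$lon, .data$lat)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$colour)) +
    ggplot2::scale_fill_identity() +
    ggplot2::geom_tile(
      data = dplyr::filter(object, .data$contour),
      fill = NA, colour = "black", linewidth = 0.3
    ) +
    ggplot2::labs(
      title = "Proportion of significant change (seasonal vs event set)",
      x = "Longitude", y = "Latitude",
      caption = "outlined cells: both proportions >= 0.5"
    )
}

#' @export
autoplot.bioclim_novelty <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$lon, .data$lat)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$category)) +
    ggplot2::scale_fill_manual(values = c(
      new = "#1b7837", past = "#8c510a", both = "grey70",
      neither = "grey95", masked = "white"
    )) +
    ggplot2::labs(
      title = sprintf("Novel / disappearing %s regimes", object$rule$variable),
      x = "Longitude", y = "Latitude", fill = NULL
    )
}

#' @export
autoplot.bioclim_clusters <- function(object, ...) {
  ggplot2::ggplot(object$labels, ggplot2::aes(.data$lon, .data$lat)) +
    ggplot2::geom_tile(ggplot2::aes(fill = factor(.data$cluster))) +
    ggplot2::labs(
      title = sprintf("KMeans climate clusters (k = %d)", object$k),
      x = "Longitude", y = "Latitude", fill = "Cluster"
    )
}
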