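# Latitude-aware surface-area accounting of event coverage.

EARTH_RADIUS_KM <- 6371

#' Spherical grid-cell areas
#'
#' Area of each cell of a regular latitude/longitude grid on a sphere:
#' `R^2 * dlambda * (sin(phi_top) - sin(phi_bottom))` with R = 6371 km, so
#' coverage statistics account for the shrinking of cells toward the pole.
#'
#' @param lat,lon cell-centre coordinates (degrees), regularly spaced.
#' @return Matrix `[lat, lon]` of areas in km^2.
#' @export
cell_areas <- function(lat, lon) {
  if (length(lat) > 1 && is.unsorted(lat, strictly = TRUE)) {
    abort("`lat` must be strictly ascending.")
  }
  if (length(lon) > 1 && is.unsorted(lon, strictly = TRUE)) {
    abort("`lon` must be strictly ascending.")
  }
  res_lat <- if (length(lat) > 1) diff(lat)[1] else attr(lat, "res") %||% 1
  res_lon <- if (length(lon) > 1) diff(lon)[1] else attr(lon, "res") %||% res_lat
  rad <- pi / 180
  band <- EARTH_RADIUS_KM^2 * res_lon * rad *
    (sin((lat + res_lat / 2) * rad) - sin((lat - res_lat / 2) * rad))
  matrix(band, length(lat), length(lon))
}

#' Event rule: a threshold test on one annual indicator
#'
#' Defines when a year at a pixel counts as an event occurrence, e.g.
#' `HWMI >= 3` or `ROS > 0`. Signed indicators (`FGS`, `FDD`) are compared
#' on their magnitude, so `FGS > 0` means "any frost occurred".
#'
#' @param variable indicator name.
#' @param comparator `">"` or `">="`.
#' @param threshold finite scalar, or a `[lat, lon]` matrix of per-pixel
#'   thresholds (used for the high-wind rule).
#' @param magnitude compare `abs(value)` instead of the signed value;
#'   default `TRUE` for `FGS`/`FDD`.
#' @return An object of class `bioclim_rule`.
#' @export
event_rule <- function(variable, comparator = c(">", ">="), threshold,
                       magnitude = variable %in% signed_indicators()) {
  comparator <- match.arg(comparator)
  if (!all(is.finite(threshold))) abort("threshold must be finite.")
  structure(
    list(
      variable = variable, comparator = comparator, threshold = threshold,
      magnitude = magnitude
    ),
    class = "bioclim_rule"
  )
}

#' @export
print.bioclim_rule <- function(x, ...) {
  thr <- if (is.matrix(x$threshold)) "<per-pixel>" else format(x$threshold)
  cat(sprintf(
    "<bioclim_rule> %s%s %s %s\n", if (x$magnitude) "|" else "",
    paste0(x$variable, if (x$magnitude) "|" else ""), x$comparator, thr
  ))
  invisible(x)
}

# evaluate a rule on one year's [lat, lon] slice
rule_holds <- function(rule, slice) {
  v <- if (rule$magnitude) abs(slice) else slice
  if (rule$comparator == ">") v > rule$threshold else v >= rule$threshold
}

#' Standard extreme-event rule table
#'
#' The rule set used for coverage and novelty mapping: `HWMI >= 3`,
#' `VPDI >= 3`, `ROS > 0`, `WWE > 0`, `FGS > 0` (in magnitude), and
#' `HWE >=` the pixel's own 90th percentile of its annual HWE series over
#' the full period (which needs the cube to compute).
#'
#' @param cube an [bioclim_cube()] (required for the HWE rule).
#' @return Named list of [event_rule()] objects.
#' @export
default_event_rules <- function(cube) {
  list(
    HWMI = event_rule("HWMI", ">=", 3),
    VPDI = event_rule("VPDI", ">=", 3),
    ROS = event_rule("ROS", ">", 0),
    WWE = event_rule("WWE", ">", 0),
    FGS = event_rule("FGS", ">", 0),
    HWE = event_rule("HWE", ">=", hwe_annual_threshold(cube))
  )
}

#' Per-pixel 90th percentile of the annual high-wind-event series
#' @param cube an [bioclim_cube()].
#' @param percentile percentile in (0, 100), default 90.
#' @return `[lat, lon]` matrix of thresholds.
#' @export
hwe_annual_threshold <- function(cube, percentile = 90) {
  apply(cube$data$HWE, c(2, 3), function(v) {
    if (all(is.na(v))) NA_real_ else {
      quantile(v, percentile / 100, names = FALSE, na.rm = TRUE)
    }
  })
}

#' Annual surface area covered by an event rule
#'
#' For each year, sums the spherical areas of the land cells where the rule
#' holds; the fraction divides by the land (or region) area. With a
#' labelled region matrix the series is stratified by region.
#'
#' @param cube an [bioclim_cube()].
#' @param rule an [event_rule()].
#' @param regions optional logical mask or label matrix `[lat, lon]`;
#'   default the whole land domain.
#' @return Tibble of class `bioclim_area_series`: `region`, `year`,
#'   `total_km2`, `fraction`.
#' @export
annual_event_area <- function(cube, rule, regions = NULL) {
  arr <- cube_variable(cube, rule$variable)
  areas <- cell_areas(cube$lat, cube$lon)
  labels <- if (is.null(regions)) {
    m <- matrix(NA_character_, length(cube$lat), length(cube$lon))
    m[cube$land] <- "all"
    m
  } else {
    region_labels(regions, cube)
  }
  labels[!cube$land] <- NA
  labs <- unique(na.omit(as.vector(labels)))
  if (!length(labs)) abort("empty region.")
  out <- purrr::map_dfr(labs, function(lab) {
    px <- labels == lab
    denom <- sum(areas[px])
    purrr::map_dfr(seq_along(cube$years), function(k) {
      hit <- rule_holds(rule, arr[k, , ]) & px
      tot <- sum(areas[hit], na.rm = TRUE)
      tibble(
        region = lab, year = cube$years[k],
        total_km2 = tot, fraction = tot / denom
      )
    })
  })
  structure(out,
    class = c("bioclim_area_series", class(out)),
    rule = rule
  )
}

#' Trends and fold change of an event-area series
#'
#' Least-squares trend of the total (or fractional) covered area per region
#' over one or more periods, plus the fold change measured on the fitted
#' line: fitted value at the last year divided by fitted value at the first
#' year (robust to single-year noise at the endpoints).
#'
#' @param series an [annual_event_area()] result.
#' @param periods named list of `c(first, last)` ranges; default full span
#'   and last 30 years.
#' @param on `"total_km2"` (default) or `"fraction"`.
#' @return Tibble: `region`, `period`, `first_year`, `last_year`, `slope`,
#'   `p_value`, `fold_change` (`NA` when the fitted value at the period
#'   start is not positive, where a ratio is meaningless).
#' @export
area_trend <- function(series, periods = NULL, on = c("total_km2", "fraction")) {
  on <- match.arg(on)
  if (is.null(periods)) {
    full <- range(series$year)
    periods <- list(
      full = full, recent = c(max(full[1], full[2] - 29L), full[2])
    )
  }
  purrr::map_dfr(unique(series$region), function(lab) {
    purrr::imap_dfr(periods, function(pr, pname) {
      d <- series[series$region == lab &
        series$year >= pr[1] & series$year <= pr[2], ]
      if (sum(is.finite(d[[on]])) < 3L) abort("degenerate series.")
      fit <- lsq_trend(d[[on]], d$year)
      f0 <- fit$intercept + fit$slope * pr[1]
      f1 <- fit$intercept + fit$slope * pr[2]
      tibble(
        region = lab, period = pname,
        first_year = pr[1], last_year = pr[2],
        slope = fit$slope, p_value = fit$p_value,
        # undefined when the fitted line starts at or below zero area
        fold_change = if (f0 <= 0) NA_real_ else f1 / f0
      )
    })
  })
}
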