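# Per-series kernels for the 11 annual bioclimatic indicators. Each kernel
# operates on one pixel's daily (or monthly) series for one accounting year;
# the cube engine in indicators-cube.R orchestrates them across the grid.

#' Find the thermal growing season in one year of daily mean temperature
#'
#' The growing season is the longest run of consecutive days with daily mean
#' temperature at or above the threshold (inclusive). Its length is the GSL
#' indicator.
#'
#' @param tmean daily mean temperature for one full year (deg C), gap-free.
#' @param threshold season threshold (deg C), default 5.
#' @return `list(start, end, length)` of the longest qualifying run; `start`
#'   and `end` are `NA` and `length` is 0 when no day qualifies.
#' @export
detect_growing_season <- function(tmean, threshold = 5) {
  if (anyNA(tmean)) abort("gap in daily series.")
  longest_true_run(tmean >= threshold)
}

#' Degree-day sum above or below a threshold
#'
#' `side = "above"` returns `sum(max(T - threshold, 0))` — the growing
#' degree-day convention, in deg C days, with strict exceedance (days at the
#' threshold contribute 0). `side = "below"` returns the signed sum
#' `sum(min(T - threshold, 0))`, so freezing degree days are `<= 0`.
#'
#' @param x daily mean temperatures over the accounting window (deg C).
#' @param threshold base temperature (deg C).
#' @param side `"above"` or `"below"`.
#' @return Degree-day sum (deg C days).
#' @export
degree_day_sum <- function(x, threshold = 5, side = c("above", "below")) {
  side <- match.arg(side)
  if (length(x) == 0L) abort("empty window.")
  if (side == "above") sum(pmax(x - threshold, 0)) else sum(pmin(x - threshold, 0))
}

#' Frost exposure during the growing season
#'
#' Signed sum of sub-freezing daily minimum skin temperatures over the days
#' of the growing season (deg C days, `<= 0`); 0 when there is no season or
#' no frost within it.
#'
#' @param tskin_min daily minimum skin temperature for the year (deg C).
#' @param season growing season as returned by [detect_growing_season()].
#' @return FGS in deg C days (non-positive).
#' @export
frost_in_growing_season <- function(tskin_min, season) {
  if (season$length == 0L) return(0)
  sum(pmin(tskin_min[season$start:season$end], 0))
}

#' Snow-cover mask from daily snow depth
#'
#' @param snow_depth daily snow depth (m), non-negative.
#' @param threshold depth (m) at and above which the cell counts as snow
#'   covered (default 0.01 m).
#' @return Logical vector.
#' @export
snow_cover_mask <- function(snow_depth, threshold = 0.01) {
  if (any(snow_depth < 0, na.rm = TRUE)) abort("negative snow depth.")
  snow_depth >= threshold
}

#' Count rain-on-snow days
#'
#' A rain-on-snow day has liquid precipitation strictly greater than the
#' threshold (default 5 mm) while the cell is snow covered.
#'
#' @param precip_liquid daily liquid precipitation (mm/day).
#' @param snow snow-cover mask aligned with `precip_liquid`.
#' @param threshold liquid precipitation threshold (mm/day), strict `>`.
#' @return Integer count.
#' @export
count_ros <- function(precip_liquid, snow, threshold = 5) {
  if (length(precip_liquid) != length(snow)) abort("misaligned series.")
  sum(snow & precip_liquid > threshold, na.rm = TRUE)
}

#' Count winter warming event days
#'
#' A winter warming day has daily mean temperature at or above the threshold
#' (default 2 deg C, inclusive) on a snow-covered cell within the
#' November-April window.
#'
#' @param tmean daily mean temperature (deg C).
#' @param snow snow-cover mask aligned with `tmean`.
#' @param in_window logical mask of days inside the seasonal window
#'   (November-April by default in the cube engine).
#' @param threshold temperature threshold (deg C), inclusive `>=`.
#' @return Integer count.
#' @export
count_wwe <- function(tmean, snow, in_window, threshold = 2) {
  if (length(tmean) != length(snow) || length(tmean) != length(in_window)) {
    abort("misaligned series.")
  }
  sum(in_window & snow & tmean >= threshold, na.rm = TRUE)
}

#' Summer warmth index from monthly mean temperatures
#'
#' Sum of the monthly mean 2-m temperatures that are above 0 deg C
#' (strictly; a month at exactly 0 contributes nothing).
#'
#' @param monthly_means 12 monthly mean temperatures (deg C).
#' @param threshold cut-off (deg C), strict; default 0.
#' @return SWI (deg C, non-negative for `threshold >= 0`).
#' @export
summer_warmth_index <- function(monthly_means, threshold = 0) {
  if (length(monthly_means) != 12L || anyNA(monthly_means)) {
    abort("need 12 non-missing monthly means.")
  }
  sum(monthly_means[monthly_means > threshold])
}

#' Snow season length
#'
#' Length (days) of the longest continuous snow-covered run within the
#' supplied (hydrological-year) window.
#'
#' @param snow snow-cover mask over the accounting window.
#' @return Integer number of days.
#' @export
snow_season_length <- function(snow) {
  longest_true_run(snow)$length
}

#' Count high wind speed events
#'
#' Days whose daily maximum wind speed strictly exceeds the pixel's
#' percentile threshold (computed from the full-period daily distribution by
#' the cube engine).
#'
#' @param wind_max daily maximum wind speed (m/s).
#' @param threshold wind-speed threshold (m/s), strict `>`.
#' @return Integer count.
#' @export
count_hwe <- function(wind_max, threshold) {
  if (all(is.na(wind_max))) abort("all-missing wind series.")
  sum(wind_max > threshold, na.rm = TRUE)
}

#' Vapor pressure deficit from temperature and dewpoint
#'
#' `e_s(T) - e_s(T_dew)` with Magnus saturation vapor pressure
#' (coefficients 17.625 and 243.04 deg C), in kPa.
#'
#' @param tmean air temperature (deg C).
#' @param dewpoint dewpoint temperature (deg C), `<= tmean`.
#' @return VPD (kPa, non-negative when `dewpoint <= tmean`).
#' @export
vapor_pressure_deficit <- function(tmean, dewpoint) {
  es <- function(t) 0.61094 * exp(17.625 * t / (t + 243.04))
  es(tmean) - es(dewpoint)
}

#' Reference climatology for the heatwave / VPD magnitude index
#'
#' Builds the two ingredients of the cumulative magnitude index for one
#' pixel: (i) a day-of-year exceedance threshold — the chosen percentile of
#' the variable pooled over a +/- `half_width`-day window across the
#' reference years — and (ii) the 25th/75th percentiles of the reference
#' years' annual maxima, used to normalize event-day magnitudes.
#'
#' @param x full daily series of the variable for one pixel.
#' @param doy,year day-of-year (1-365) and year of each element of `x`.
#' @param ref_years length-2 year range of the reference period.
#' @param percentile exceedance percentile (default 90).
#' @param half_width half-width (days) of the day-of-year pooling window
#'   (default 15).
#' @return `list(thresholds, q25, q75)` where `thresholds` has length 365.
#' @export
magnitude_reference <- function(x, doy, year, ref_years, percentile = 90,
                                half_width = 15) {
  check_number(percentile, "percentile", min = 0, max = 100,
    strict_min = TRUE, strict_max = TRUE
  )
  in_ref <- year >= ref_years[1] & year <= ref_years[2]
  if (!any(in_ref)) abort("reference period outside the data span.")
  xr <- x[in_ref]
  dr <- doy[in_ref]
  # values by day-of-year, pooled over the window (wrap around year end)
  by_doy <- split(xr, dr)
  thresholds <- vapply(1:365, function(d) {
    win <- ((d - half_width):(d + half_width) - 1L) %% 365L + 1L
    quantile(unlist(by_doy[as.character(win)], use.names = FALSE),
      percentile / 100,
      names = FALSE, na.rm = TRUE
    )
  }, numeric(1))
  ann_max <- vapply(
    split(xr, year[in_ref]), max, numeric(1),
    na.rm = TRUE
  )
  q <- quantile(ann_max, c(0.25, 0.75), names = FALSE)
  list(thresholds = thresholds, q25 = q[1], q75 = q[2])
}

#' Cumulative magnitude index of the strongest event of the year
#'
#' Russo-family construction used for both the heatwave magnitude index
#' (on daily maximum temperature) and the VPD magnitude index: days within
#' the summer window whose value strictly exceeds the day-of-year reference
#' threshold form events when at least `min_run` consecutive days exceed;
#' each event day `d` contributes `max(0, (x_d - q25)/(q75 - q25))` where
#' the quartiles come from the reference-period annual maxima; the index is
#' the largest event sum of the year (the strongest event), or 0 when no
#' event occurs.
#'
#' @param x daily series for one year.
#' @param doy day-of-year (1-365) of each element.
#' @param reference output of [magnitude_reference()].
#' @param summer_doys integer vector of day-of-year values forming the
#'   seasonal window (default May-September).
#' @param min_run minimum run length of exceedance days (default 3).
#' @param eps if the reference quartiles are degenerate (`q75 == q25`) an
#'   error is raised unless `eps > 0`, in which case `eps` replaces the
#'   inter-quartile range with a warning.
#' @return The index (non-negative scalar).
#' @export
magnitude_index <- function(x, doy, reference, summer_doys = summer_window(),
                            min_run = 3, eps = 0) {
  iqr <- reference$q75 - reference$q25
  if (iqr <= 0) {
    if (eps > 0) {
      warn("degenerate reference quartiles; using configured epsilon.")
      iqr <- eps
    } else {
      abort("degenerate reference: q75 == q25.",
        class = "bioclim_degenerate_reference"
      )
    }
  }
  exceed <- x > reference$thresholds[doy] & doy %in% summer_doys
  exceed[is.na(exceed)] <- FALSE
  r <- rle(exceed)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values & r$lengths >= min_run)
  if (!length(keep)) return(0)
  sums <- vapply(keep, function(i) {
    d <- starts[i]:ends[i]
    sum(pmax((x[d] - reference$q25) / iqr, 0))
  }, numeric(1))
  max(sums)
}

#' Day-of-year values of the May-September summer window
#' @param months integer months included (default 5:9).
#' @return Integer vector of day-of-year values.
#' @export
summer_window <- function(months = 5:9) {
  cal <- noleap_calendar(c(2001L, 2001L))
  cal$doy[cal$month %in% months]
}
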