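#' Configuration for the annual indicator engine
#'
#' Thresholds, windows and reference periods for the 11 bioclimatic
#' indicators. Defaults follow the standard definitions: 5 deg C for the
#' growing season and degree days, 2 deg C (inclusive) during November-April
#' for winter warming events, strict 5 mm liquid precipitation for
#' rain-on-snow, strict 0 deg C monthly means for the summer warmth index,
#' and the 90th percentile for wind events and the magnitude indices.
#'
#' @param gsl_threshold growing-season temperature threshold (deg C).
#' @param gdd_threshold base temperature of the growing degree-day sum.
#' @param wwe_threshold winter-warming temperature threshold (deg C,
#'   inclusive).
#' @param wwe_months months of the winter-warming window (default Nov-Apr).
#' @param ros_threshold liquid precipitation threshold (mm/day, strict).
#' @param swi_threshold monthly-mean threshold of the summer warmth index.
#' @param snow_depth_threshold snow-cover depth threshold (m).
#' @param hwe_percentile percentile of the full-period daily wind
#'   distribution defining a high wind event (strict exceedance).
#' @param min_run minimum consecutive exceedance days forming a heatwave /
#'   VPD event.
#' @param magnitude_percentile day-of-year exceedance percentile of the
#'   magnitude indices.
#' @param magnitude_half_width half-width (days) of the day-of-year pooling
#'   window.
#' @param summer_months months of the heatwave/VPD season (default May-Sep).
#' @param reference_years length-2 year range of the magnitude-index
#'   reference period, or `NULL` for the first 30 data years.
#' @param hydro_start_month first month of the hydrological year (default
#'   July); freezing degree days, snow season length, rain-on-snow and
#'   winter warming events are accounted on hydrological years labelled by
#'   their January year so winters are never split.
#' @param magnitude_eps replacement inter-quartile range when the magnitude
#'   reference is degenerate; 0 (the default) raises an error instead.
#' @return An object of class `bioclim_indicator_config`.
#' @export
indicator_config <- function(gsl_threshold = 5, gdd_threshold = 5,
                             wwe_threshold = 2,
                             wwe_months = c(11L, 12L, 1L, 2L, 3L, 4L),
                             ros_threshold = 5, swi_threshold = 0,
                             snow_depth_threshold = 0.01,
                             hwe_percentile = 90, min_run = 3,
                             magnitude_percentile = 90,
                             magnitude_half_width = 15,
                             summer_months = 5:9,
                             reference_years = NULL,
                             hydro_start_month = 7L,
                             magnitude_eps = 0) {
  for (nm in c(
    "gsl_threshold", "gdd_threshold", "wwe_threshold", "ros_threshold",
    "swi_threshold", "snow_depth_threshold", "magnitude_half_width",
    "min_run", "magnitude_eps"
  )) {
    check_number(get(nm), nm)
  }
  check_number(hwe_percentile, "hwe_percentile", 0, 100, TRUE, TRUE)
  check_number(magnitude_percentile, "magnitude_percentile", 0, 100, TRUE, TRUE)
  structure(
    list(
      gsl_threshold = gsl_threshold, gdd_threshold = gdd_threshold,
      wwe_threshold = wwe_threshold, wwe_months = as.integer(wwe_months),
      ros_threshold = ros_threshold, swi_threshold = swi_threshold,
      snow_depth_threshold = snow_depth_threshold,
      hwe_percentile = hwe_percentile, min_run = min_run,
      magnitude_percentile = magnitude_percentile,
      magnitude_half_width = magnitude_half_width,
      summer_months = as.integer(summer_months),
      reference_years = reference_years,
      hydro_start_month = as.integer(hydro_start_month),
      magnitude_eps = magnitude_eps
    ),
    class = "bioclim_indicator_config"
  )
}

#' Names of the 11 annual bioclimatic indicators
#' @return Character vector.
#' @export
bioclim_indicator_vars <- function() {
  c(
    "GDD", "GSL", "FGS", "FDD", "SSL", "SWI", "ROS", "WWE", "HWMI",
    "VPDI", "HWE"
  )
}

# variables whose stored values are signed negative sums
signed_indicators <- function() c("FGS", "FDD")

#' Annual indicator cube container
#'
#' Per-year, per-pixel values of the 11 bioclimatic indicators. Ranges are
#' validated: season lengths in `[0, 365]`, event counts non-negative
#' integers, degree-day and magnitude indices non-negative, and the frost
#' variables (`FGS`, `FDD`) non-positive under the signed convention.
#' Masked (ocean/ice) pixels are `NA`, never zero.
#'
#' @param years integer vector of years.
#' @param lat,lon coordinate vectors.
#' @param data named list of `[year, lat, lon]` arrays, one per indicator.
#' @param land logical land mask `[lat, lon]`.
#' @param config the `bioclim_indicator_config` used (provenance).
#' @return An object of class `bioclim_cube`.
#' @export
bioclim_cube <- function(years, lat, lon, data, land = NULL, config = NULL) {
  missing_vars <- setdiff(bioclim_indicator_vars(), names(data))
  if (length(missing_vars)) {
    abort(sprintf(
      "missing variable: %s", paste(missing_vars, collapse = ", ")
    ), class = "bioclim_missing_variable")
  }
  dims <- c(length(years), length(lat), length(lon))
  for (v in names(data)) {
    if (!identical(dim(data[[v]]), as.integer(dims))) {
      abort(sprintf("array `%s` has wrong dimensions", v),
        class = "bioclim_bad_dimensions"
      )
    }
  }
  if (is.null(land)) land <- matrix(TRUE, length(lat), length(lon))
  rng_ok <- function(x, lo = -Inf, hi = Inf) {
    all(x >= lo & x <= hi, na.rm = TRUE)
  }
  stopifnot(
    rng_ok(data$GSL, 0, 365), rng_ok(data$SSL, 0, 365),
    rng_ok(data$ROS, 0), rng_ok(data$WWE, 0), rng_ok(data$HWE, 0),
    rng_ok(data$GDD, 0), rng_ok(data$SWI, 0), rng_ok(data$HWMI, 0),
    rng_ok(data$VPDI, 0), rng_ok(data$FGS, -Inf, 0),
    rng_ok(data$FDD, -Inf, 0)
  )
  structure(
    list(
      years = as.integer(years), lat = lat, lon = lon, data = data,
      land = land, config = config
    ),
    class = "bioclim_cube"
  )
}

#' @export
print.bioclim_cube <- function(x, ...) {
  cat("<bioclim_cube>\n")
  cat(sprintf(
    "  %d years (%d-%d) x %d lat x %d lon, %d land cells\n",
    length(x$years), min(x$years), max(x$years),
    length(x$lat), length(x$lon), sum(x$land)
  ))
  cat(" ", paste(names(x$data), collapse = ", "), "\n")
  invisible(x)
}

#' Long-format view of an annual indicator cube
#' @param x an `bioclim_cube`.
#' @param ... unused.
#' @return Tibble with columns year, lat, lon, variable, value.
#' @export
tidy.bioclim_cube <- function(x, ...) {
  grid <- expand.grid(lat = x$lat, lon = x$lon)
  purrr::map_dfr(names(x$data), function(v) {
    tibble(
      year = rep(x$years, times = nrow(grid)),
      lat = rep(grid$lat, each = length(x$years)),
      lon = rep(grid$lon, each = length(x$years)),
      variable = v,
      value = as.vector(x$data[[v]])
    )
  })
}

# extract one pixel's series from a [time, lat, lon] array
pixel_series <- function(arr, i, j) arr[, i, j]

#' Compute the 11 annual bioclimatic indicators from daily weather
#'
#' Runs every indicator for every land pixel and year. Calendar-year
#' variables: GDD, GSL, FGS, SWI, HWMI, VPDI, HWE. Hydrological-year
#' variables (labelled by the January year): FDD, SSL, ROS, WWE; these are
#' `NA` for the first data year, whose early winter half lies before the
#' record starts. The heatwave magnitude index runs on daily maximum
#' temperature and the VPD magnitude index on vapor pressure deficit derived
#' from mean temperature and dewpoint via the Magnus formula.
#'
#' @param weather an [bioclim_weather()] object.
#' @param config an [indicator_config()].
#' @return An [bioclim_cube()].
#' @export
compute_annual_indicators <- function(weather, config = indicator_config()) {
  if (!inherits(weather, "bioclim_weather")) {
    abort("`weather` must be an bioclim_weather object.")
  }
  cfg <- config
  time <- weather$time
  years <- sort(unique(time$year))
  ny <- length(years)
  nlat <- length(weather$lat)
  nlon <- length(weather$lon)
  if (is.null(cfg$reference_years)) {
    cfg$reference_years <- c(years[1], min(years[1] + 29L, years[ny]))
  }
  check_period(cfg$reference_years, years, "reference_years")

  # per-year index sets, computed once
  cal_idx <- lapply(years, function(y) which(time$year == y))
  hydro_idx <- lapply(years, function(y) {
    which((time$year == y - 1L & time$month >= cfg$hydro_start_month) |
      (time$year == y & time$month < cfg$hydro_start_month))
  })
  hydro_complete <- vapply(
    hydro_idx, function(i) length(i) == 365L, logical(1)
  )
  month_of <- time$month
  doy_of <- time$doy
  summer_doys <- summer_window(cfg$summer_months)

  out <- lapply(bioclim_indicator_vars(), function(v) {
    array(NA_real_, dim = c(ny, nlat, nlon))
  })
  names(out) <- bioclim_indicator_vars()

  for (j in seq_len(nlon)) {
    for (i in seq_len(nlat)) {
      if (!weather$land[i, j]) next
      tmean <- pixel_series(weather$data$tmean, i, j)
      tmax <- pixel_series(weather$data$tmax, i, j)
      tskin <- pixel_series(weather$data$tskin_min, i, j)
      liquid <- pixel_series(weather$data$precip_liquid, i, j)
      snowd <- pixel_series(weather$data$snow_depth, i, j)
      wind <- pixel_series(weather$data$wind_max, i, j)
      dew <- pixel_series(weather$data$dewpoint, i, j)
      snow <- snow_cover_mask(snowd, cfg$snow_depth_threshold)
      vpd <- vapor_pressure_deficit(tmean, dew)

      hw_ref <- magnitude_reference(
        tmax, doy_of, time$year, cfg$reference_years,
        cfg$magnitude_percentile, cfg$magnitude_half_width
      )
      vpd_ref <- magnitude_reference(
        vpd, doy_of, time$year, cfg$reference_years,
        cfg$magnitude_percentile, cfg$magnitude_half_width
      )
      hwe_thr <- quantile(wind, cfg$hwe_percentile / 100, names = FALSE)

      for (k in seq_len(ny)) {
        ci <- cal_idx[[k]]
        season <- detect_growing_season(tmean[ci], cfg$gsl_threshold)
        out$GSL[k, i, j] <- season$length
        out$GDD[k, i, j] <- if (season$length == 0L) 0 else {
          degree_day_sum(
            tmean[ci][season$start:season$end], cfg$gdd_threshold, "above"
          )
        }
        out$FGS[k, i, j] <- frost_in_growing_season(tskin[ci], season)
        mm <- vapply(
          1:12, function(m) mean(tmean[ci][month_of[ci] == m]), numeric(1)
        )
        out$SWI[k, i, j] <- summer_warmth_index(mm, cfg$swi_threshold)
        out$HWMI[k, i, j] <- magnitude_index(
          tmax[ci], doy_of[ci], hw_ref, summer_doys, cfg$min_run,
          cfg$magnitude_eps
        )
        out$VPDI[k, i, j] <- magnitude_index(
          vpd[ci], doy_of[ci], vpd_ref, summer_doys, cfg$min_run,
          cfg$magnitude_eps
        )
        out$HWE[k, i, j] <- count_hwe(wind[ci], hwe_thr)

        if (hydro_complete[k]) {
          hi <- hydro_idx[[k]]
          out$FDD[k, i, j] <- degree_day_sum(tmean[hi], 0, "below")
          out$SSL[k, i, j] <- snow_season_length(snow[hi])
          out$ROS[k, i, j] <- count_ros(
            liquid[hi], snow[hi], cfg$ros_threshold
          )
          out$WWE[k, i, j] <- count_wwe(
            tmean[hi], snow[hi], month_of[hi] %in% cfg$wwe_months,
            cfg$wwe_threshold
          )
        }
      }
    }
  }
  bioclim_cube(years, weather$lat, weather$lon, out, weather$land, cfg)
}
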