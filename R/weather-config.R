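#' Configuration for the synthetic daily weather generator
#'
#' Defines the grid, time span, and the stochastic model for every
#' meteorological field the generator emits. Defaults describe a small
#' high-latitude domain with a realistic latitudinal temperature gradient,
#' seasonal cycle, AR(1) day-to-day persistence, stochastic precipitation
#' with a temperature phase split, a degree-day snowpack, Weibull wind
#' extremes, and a dewpoint depression model.
#'
#' @param lat_range,lon_range numeric length-2, domain edges in degrees
#'   (cells are centred inside the range).
#' @param resolution grid resolution in degrees (> 0).
#' @param years integer length-2, first and last simulated year.
#' @param temp_base mean annual 2-m temperature at 60 deg N (deg C).
#' @param temp_lapse cooling per degree latitude northward (deg C / deg lat).
#' @param seasonal_amp amplitude of the seasonal temperature cycle (deg C);
#'   the cycle is `seasonal_amp * cos(2*pi*(doy - peak_doy)/365)`.
#' @param peak_doy day of year of the warm peak (365-day calendar).
#' @param trend imposed linear warming trend (deg C per decade).
#' @param trend_recent additional warming trend (deg C per decade) applied
#'   from `split_year` onward; non-zero values give an accelerating scenario.
#' @param split_year first year of the recent period used by `trend_recent`
#'   and by step-change scenarios.
#' @param ar1 AR(1) coefficient of daily temperature noise, in `[0, 1)`.
#' @param noise_sd marginal standard deviation of daily temperature noise
#'   (deg C).
#' @param diurnal_range mean daily range `tmax - tmin` (deg C).
#' @param diurnal_sd day-to-day variability of the half range (deg C).
#' @param skin_offset how far nightly minimum skin temperature sits below
#'   `tmin` (deg C, >= 0).
#' @param wet_prob probability a day is wet, in `[0, 1]`.
#' @param precip_shape,precip_scale gamma distribution of wet-day totals
#'   (mm/day).
#' @param phase_split temperature (deg C) at and above which precipitation
#'   falls as rain; below it, as snow.
#' @param melt_factor degree-day snowmelt factor (mm water equivalent per
#'   deg C per day above freezing).
#' @param snow_density snowpack density used to convert water equivalent to
#'   depth (kg/m^3).
#' @param snow_depth_threshold depth (m) at and above which a cell counts as
#'   snow covered.
#' @param wind_shape,wind_scale Weibull distribution of daily maximum 10-m
#'   wind speed (m/s).
#' @param dewpoint_dep_mean,dewpoint_dep_sd dewpoint depression below daily
#'   mean temperature (deg C); draws are floored at 0 so dewpoint never
#'   exceeds temperature.
#' @param step_offset temperature offset (deg C) added from `split_year`
#'   onward (step-change scenarios; 0 disables).
#' @param step_precip_factor multiplier on precipitation from `split_year`
#'   onward.
#' @param step_wind_offset wind-speed offset (m/s) from `split_year` onward.
#' @param step_skin_offset offset (deg C) added to the minimum skin
#'   temperature from `split_year` onward (negative values deepen nightly
#'   ground frost, e.g. reduced snow insulation).
#' @param step_pixels `NULL` (whole domain) or `list(lat =, lon =)` of grid
#'   indices delimiting the block the step terms apply to.
#' @param events `NULL` or a data frame with columns `year`, `month`, `day`,
#'   `lat`, `lon` (grid indices): days forced to be warm (2-m mean 3 deg C),
#'   snow covered, and rainy (6 mm liquid), used to inject rain-on-snow /
#'   winter-warming forcing at known pixels.
#' @param seed integer master seed; each meteorological variable draws from
#'   its own stream derived from `(seed, variable name)`.
#'
#' @return An object of class `bioclim_config` (a validated list).
#' @seealso [generate_weather()], [scenario_preset()]
#' @export
weather_config <- function(lat_range = c(60, 70), lon_range = c(20, 30),
                           resolution = 1, years = c(1950, 2022),
                           temp_base = 2, temp_lapse = 0.8,
                           seasonal_amp = 15, peak_doy = 200,
                           trend = 0, trend_recent = 0, split_year = 1993,
                           ar1 = 0.7, noise_sd = 3,
                           diurnal_range = 6, diurnal_sd = 1,
                           skin_offset = 1,
                           wet_prob = 0.35, precip_shape = 0.7,
                           precip_scale = 4,
                           phase_split = 1, melt_factor = 3,
                           snow_density = 100, snow_depth_threshold = 0.01,
                           wind_shape = 2, wind_scale = 7,
                           dewpoint_dep_mean = 2, dewpoint_dep_sd = 1.5,
                           step_offset = 0, step_precip_factor = 1,
                           step_wind_offset = 0, step_skin_offset = 0,
                           step_pixels = NULL,
                           events = NULL, seed = 1L) {
  cfg <- list(
    lat_range = lat_range, lon_range = lon_range, resolution = resolution,
    years = as.integer(years),
    temp_base = temp_base, temp_lapse = temp_lapse,
    seasonal_amp = seasonal_amp, peak_doy = peak_doy,
    trend = trend, trend_recent = trend_recent,
    split_year = as.integer(split_year),
    ar1 = ar1, noise_sd = noise_sd,
    diurnal_range = diurnal_range, diurnal_sd = diurnal_sd,
    skin_offset = skin_offset,
    wet_prob = wet_prob, precip_shape = precip_shape,
    precip_scale = precip_scale,
    phase_split = phase_split, melt_factor = melt_factor,
    snow_density = snow_density,
    snow_depth_threshold = snow_depth_threshold,
    wind_shape = wind_shape, wind_scale = wind_scale,
    dewpoint_dep_mean = dewpoint_dep_mean, dewpoint_dep_sd = dewpoint_dep_sd,
    step_offset = step_offset, step_precip_factor = step_precip_factor,
    step_wind_offset = step_wind_offset,
    step_skin_offset = step_skin_offset, step_pixels = step_pixels,
    events = events, seed = as.integer(seed)
  )
  class(cfg) <- "bioclim_config"
  validate_weather_config(cfg)
}

validate_weather_config <- function(cfg) {
  check_number(cfg$resolution, "resolution", min = 0, strict_min = TRUE)
  if (length(cfg$years) != 2L || cfg$years[2] < cfg$years[1]) {
    abort("`years` must be c(first, last) with last >= first.")
  }
  if (diff(cfg$lat_range) < cfg$resolution ||
      diff(cfg$lon_range) < cfg$resolution) {
    abort("grid ranges must span at least one cell.")
  }
  check_number(cfg$ar1, "ar1", min = 0, max = 1, strict_max = TRUE)
  check_number(cfg$noise_sd, "noise_sd", min = 0)
  check_number(cfg$seasonal_amp, "seasonal_amp", min = 0)
  check_number(cfg$temp_base, "temp_base")
  check_number(cfg$temp_lapse, "temp_lapse")
  check_number(cfg$trend, "trend")
  check_number(cfg$trend_recent, "trend_recent")
  check_number(cfg$peak_doy, "peak_doy", min = 1, max = 365)
  check_number(cfg$diurnal_range, "diurnal_range", min = 0)
  check_number(cfg$diurnal_sd, "diurnal_sd", min = 0)
  check_number(cfg$skin_offset, "skin_offset", min = 0)
  check_number(cfg$wet_prob, "wet_prob", min = 0, max = 1)
  check_number(cfg$precip_shape, "precip_shape", min = 0, strict_min = TRUE)
  check_number(cfg$precip_scale, "precip_scale", min = 0, strict_min = TRUE)
  check_number(cfg$phase_split, "phase_split")
  check_number(cfg$melt_factor, "melt_factor", min = 0)
  check_number(cfg$snow_density, "snow_density", min = 1)
  check_number(cfg$snow_depth_threshold, "snow_depth_threshold", min = 0)
  check_number(cfg$wind_shape, "wind_shape", min = 0, strict_min = TRUE)
  check_number(cfg$wind_scale, "wind_scale", min = 0, strict_min = TRUE)
  check_number(cfg$dewpoint_dep_mean, "dewpoint_dep_mean", min = 0)
  check_number(cfg$dewpoint_dep_sd, "dewpoint_dep_sd", min = 0)
  check_number(cfg$step_offset, "step_offset")
  check_number(cfg$step_precip_factor, "step_precip_factor", min = 0)
  check_number(cfg$step_wind_offset, "step_wind_offset")
  check_number(cfg$step_skin_offset %||% 0, "step_skin_offset")
  if (!is.null(cfg$events)) {
    need <- c("year", "month", "day", "lat", "lon")
    if (!all(need %in% names(cfg$events))) {
      abort("`events` must have columns year, month, day, lat, lon.")
    }
  }
  cfg
}

#' @export
print.bioclim_config <- function(x, ...) {
  cat("<bioclim_config>\n")
  cat(sprintf(
    "  grid: %.1f-%.1f N x %.1f-%.1f E @ %.2f deg, years %d-%d\n",
    x$lat_range[1], x$lat_range[2], x$lon_range[1], x$lon_range[2],
    x$resolution, x$years[1], x$years[2]
  ))
  cat(sprintf(
    "  trend %.2f C/decade (+%.2f after %d), step %.2f C, seed %d\n",
    x$trend, x$trend_recent, x$split_year, x$step_offset, x$seed
  ))
  invisible(x)
}

#' Named scenario presets for the weather generator
#'
#' Convenience constructors for the study scenarios used throughout the
#' package tests and examples.
#'
#' * `"stationary"`: all trend and step terms zero.
#' * `"warming"`: linear warming trend (default 0.5 deg C per decade), with
#'   an optional extra recent trend to make the warming accelerate.
#' * `"step_change"`: a constant offset applied from `split_year` onward,
#'   optionally restricted to a pixel block and combined with precipitation
#'   scaling and a wind offset so event-type indicators respond too.
#' * `"event_injection"`: precipitation falls entirely as snow (phase
#'   threshold +99 deg C) so rain-on-snow days can only occur where and when
#'   injected; injections are placed in January-March so calendar and
#'   hydrological year labels coincide.
#'
#' @param name preset name.
#' @param config base configuration to modify.
#' @param trend,trend_recent warming rates (deg C/decade), `"warming"` only.
#' @param split_year first year of the recent / post-change period.
#' @param offset temperature step (deg C), `"step_change"` only.
#' @param precip_factor,wind_offset,skin_offset additional step forcing
#'   (`"step_change"`): precipitation scaling, wind offset (m/s) and a skin
#'   temperature offset (deg C).
#' @param pixels `list(lat =, lon =)` block indices for the step, or `NULL`
#'   for the whole domain.
#' @param years,lat,lon years and pixel indices of injected events
#'   (`"event_injection"`).
#' @param n_per_year number of injected event days per year per pixel.
#' @return A modified `bioclim_config`.
#' @export
scenario_preset <- function(name = c("stationary", "warming", "step_change",
                                     "event_injection"),
                            config = weather_config(),
                            trend = 0.5, trend_recent = 0, split_year = 1993,
                            offset = 2, precip_factor = 1, wind_offset = 0,
                            skin_offset = 0, pixels = NULL,
                            years = integer(), lat = 1L, lon = 1L,
                            n_per_year = 3L) {
  name <- match.arg(name)
  cfg <- config
  cfg$split_year <- as.integer(split_year)
  if (name == "stationary") {
    cfg$trend <- 0
    cfg$trend_recent <- 0
    cfg$step_offset <- 0
    cfg$step_precip_factor <- 1
    cfg$step_wind_offset <- 0
    cfg$events <- NULL
  } else if (name == "warming") {
    cfg$trend <- trend
    cfg$trend_recent <- trend_recent
    cfg$step_offset <- 0
  } else if (name == "step_change") {
    cfg$trend <- 0
    cfg$trend_recent <- 0
    cfg$step_offset <- offset
    cfg$step_precip_factor <- precip_factor
    cfg$step_wind_offset <- wind_offset
    cfg$step_skin_offset <- skin_offset
    cfg$step_pixels <- pixels
  } else if (name == "event_injection") {
    cfg$trend <- 0
    cfg$trend_recent <- 0
    cfg$step_offset <- 0
    cfg$phase_split <- 99 # all precipitation solid except injected days
    if (length(years)) {
      px <- expand.grid(lat = lat, lon = lon)
      days <- seq(10L, by = 30L, length.out = n_per_year) # Jan-Mar
      ev <- expand.grid(
        year = as.integer(years), doy = days,
        px_i = seq_len(nrow(px))
      )
      cal <- noleap_calendar(c(2001L, 2001L))
      cfg$events <- tibble(
        year = ev$year,
        month = cal$month[ev$doy],
        day = cal$day[ev$doy],
        lat = px$lat[ev$px_i],
        lon = px$lon[ev$px_i]
      )
    }
  }
  validate_weather_config(cfg)
}
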