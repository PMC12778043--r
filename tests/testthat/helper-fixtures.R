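# Small in-code fixtures shared across tests.

# fast tiny weather: 1-degree grid, few years, modest noise
tiny_config <- function(nlat = 3, nlon = 3, years = c(1950, 1952),
                        seed = 42, ...) {
  weather_config(
    lat_range = c(60, 60 + nlat), lon_range = c(20, 20 + nlon),
    resolution = 1, years = years, seed = seed, ...
  )
}

tiny_weather <- function(...) generate_weather(tiny_config(...))

# hand-built single-pixel weather from explicit daily series
manual_weather <- function(tmean, years = c(2000, 2000),
                           tskin_min = tmean - 5,
                           precip_total = rep(0, length(tmean)),
                           precip_liquid = precip_total,
                           snow_depth = rep(0, length(tmean)),
                           wind_max = rep(5, length(tmean)),
                           dewpoint = tmean - 2) {
  time <- noleap_calendar(years)
  stopifnot(length(tmean) == nrow(time))
  shape <- function(x) array(x, dim = c(length(x), 1, 1))
  bioclim_weather(
    lat = 65, lon = 25, time = time,
    data = list(
      tmean = shape(tmean), tmin = shape(tmean - 5),
      tmax = shape(tmean + 5), tskin_min = shape(tskin_min),
      precip_total = shape(precip_total),
      precip_liquid = shape(pmin(precip_liquid, precip_total)),
      snow_depth = shape(snow_depth), wind_max = shape(wind_max),
      dewpoint = shape(dewpoint)
    )
  )
}

# hand-built indicator cube with a single overridden variable; everything
# else set to legal constants
manual_cube <- function(variable, values, years = seq_len(dim(values)[1]),
                        lat = 60.5 + seq_len(dim(values)[2]) - 1,
                        lon = 20.5 + seq_len(dim(values)[3]) - 1,
                        land = NULL) {
  ny <- length(years)
  dims <- c(ny, length(lat), length(lon))
  zero <- array(0, dims)
  data <- list(
    GDD = zero, GSL = zero, FGS = zero, FDD = zero, SSL = zero,
    SWI = zero, ROS = zero, WWE = zero, HWMI = zero, VPDI = zero,
    HWE = zero
  )
  data[[variable]] <- array(values, dims)
  bioclim_cube(years, lat, lon, data, land = land)
}
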