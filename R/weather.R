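#' Gridded daily weather container
#'
#' Bundles daily meteorological fields on a regular latitude/longitude grid
#' with a contiguous 365-day calendar. Arrays are dimensioned
#' `[time, lat, lon]`. Construction validates the physical invariants:
#' `tmin <= tmean <= tmax`, `0 <= precip_liquid <= precip_total`,
#' `snow_depth >= 0`, dewpoint never above the mean temperature, and
#' coordinate/array shape consistency.
#'
#' @param lat,lon cell-centre coordinates (degrees), `lat` ascending.
#' @param time tibble with columns `year`, `month`, `day`, `doy` as built by
#'   [noleap_calendar()].
#' @param data named list of arrays `[n_time, n_lat, n_lon]`; required
#'   variables: tmean, tmin, tmax, tskin_min, precip_total, precip_liquid,
#'   snow_depth, wind_max, dewpoint (see [bioclim_weather_vars()]).
#' @param land logical matrix `[n_lat, n_lon]`; `FALSE` marks ocean/ice
#'   cells that every downstream stage treats as missing.
#' @param config optional `bioclim_config` provenance record.
#' @return An object of class `bioclim_weather`.
#' @export
bioclim_weather <- function(lat, lon, time, data, land = NULL, config = NULL) {
  if (is.unsorted(lat, strictly = TRUE)) abort("`lat` must be ascending.")
  if (is.unsorted(lon, strictly = TRUE)) abort("`lon` must be ascending.")
  missing_vars <- setdiff(bioclim_weather_vars(), names(data))
  if (length(missing_vars)) {
    abort(sprintf(
      "missing variable: %s", paste(missing_vars, collapse = ", ")
    ), class = "bioclim_missing_variable")
  }
  nt <- nrow(time)
  dims <- c(nt, length(lat), length(lon))
  for (v in names(data)) {
    if (!identical(dim(data[[v]]), as.integer(dims))) {
      abort(sprintf(
        "array `%s` has dimensions (%s), expected (%s)",
        v, paste(dim(data[[v]]), collapse = ", "),
        paste(dims, collapse = ", ")
      ), class = "bioclim_bad_dimensions")
    }
  }
  cal <- noleap_calendar(range(time$year))
  if (!identical(as.data.frame(cal), as.data.frame(time[names(cal)]))) {
    abort("`time` must be a gap-free 365-day calendar.",
      class = "bioclim_bad_calendar"
    )
  }
  if (is.null(land)) land <- matrix(TRUE, length(lat), length(lon))
  ok <- function(x) all(x, na.rm = TRUE)
  if (!ok(data$tmin <= data$tmean) || !ok(data$tmean <= data$tmax)) {
    abort("temperature ordering tmin <= tmean <= tmax violated.")
  }
  if (!ok(data$precip_liquid >= 0) ||
      !ok(data$precip_liquid <= data$precip_total + 1e-9)) {
    abort("precipitation must satisfy 0 <= liquid <= total.")
  }
  if (!ok(data$snow_depth >= 0)) abort("snow_depth must be non-negative.")
  if (!ok(data$dewpoint <= data$tmean + 1e-9)) {
    abort("dewpoint must not exceed tmean.")
  }
  structure(
    list(
      lat = lat, lon = lon, time = time, data = data,
      land = land, config = config
    ),
    class = "bioclim_weather"
  )
}

#' Names of the daily variables an `bioclim_weather` object carries
#' @return Character vector of variable names.
#' @export
bioclim_weather_vars <- function() {
  c(
    "tmean", "tmin", "tmax", "tskin_min", "precip_total", "precip_liquid",
    "snow_depth", "wind_max", "dewpoint"
  )
}

#' @export
print.bioclim_weather <- function(x, ...) {
  cat("<bioclim_weather>\n")
  cat(sprintf(
    "  %d days (%d-%d) x %d lat x %d lon, %d land cells\n",
    nrow(x$time), min(x$time$year), max(x$time$year),
    length(x$lat), length(x$lon), sum(x$land)
  ))
  cat(" ", paste(names(x$data), collapse = ", "), "\n")
  invisible(x)
}

#' @describeIn bioclim_weather long-format tibble view (one row per day,
#'   cell and variable); intended for small objects and plotting.
#' @param x an `bioclim_weather` object.
#' @param ... unused.
#' @export
tidy.bioclim_weather <- function(x, ...) {
  grid <- expand.grid(lat = x$lat, lon = x$lon)
  purrr::map_dfr(names(x$data), function(v) {
    tibble(
      year = rep(x$time$year, times = nrow(grid)),
      doy = rep(x$time$doy, times = nrow(grid)),
      lat = rep(grid$lat, each = nrow(x$time)),
      lon = rep(grid$lon, each = nrow(x$time)),
      variable = v,
      value = as.vector(x$data[[v]])
    )
  })
}

#' Generate synthetic ERA5-Land-like daily gridded weather
#'
#' Simulates every field required by the indicator engine on the grid and
#' span given in `config`. Daily mean temperature is a deterministic
#' climatology (latitudinal gradient + seasonal cosine + imposed trends and
#' step offsets) plus AR(1) noise; precipitation is Bernoulli-gamma with a
#' temperature phase split; the snowpack integrates solid precipitation and
#' degree-day melt; wind is Weibull; dewpoint sits a non-negative depression
#' below the mean temperature. Each variable uses its own RNG stream derived
#' from `(seed, variable name)`, so output is reproducible and adding a new
#' variable leaves existing ones untouched.
#'
#' @param config an [weather_config()] object.
#' @return An [bioclim_weather()] object.
#' @export
generate_weather <- function(config) {
  cfg <- validate_weather_config(config)
  res <- cfg$resolution
  lat <- seq(cfg$lat_range[1] + res / 2, cfg$lat_range[2] - res / 2 + 1e-9,
    by = res
  )
  lon <- seq(cfg$lon_range[1] + res / 2, cfg$lon_range[2] - res / 2 + 1e-9,
    by = res
  )
  nlat <- length(lat)
  nlon <- length(lon)
  npix <- nlat * nlon
  time <- noleap_calendar(cfg$years)
  nt <- nrow(time)
  lat_px <- rep(lat, times = nlon) # pixel order: lat fastest (column-major)

  step_px <- rep(TRUE, npix)
  if (!is.null(cfg$step_pixels)) {
    m <- matrix(FALSE, nlat, nlon)
    m[cfg$step_pixels$lat, cfg$step_pixels$lon] <- TRUE
    step_px <- as.vector(m)
  }
  post <- time$year >= cfg$split_year

  # deterministic temperature climatology [nt x npix]
  seas <- cfg$seasonal_amp * cos(2 * pi * (time$doy - cfg$peak_doy) / 365)
  yr0 <- cfg$years[1]
  tr <- cfg$trend / 10 * (time$year - yr0) +
    cfg$trend_recent / 10 * pmax(time$year - cfg$split_year, 0)
  clim_t <- seas + tr # time component
  clim <- outer(clim_t, rep(1, npix)) +
    outer(rep(1, nt), cfg$temp_base - cfg$temp_lapse * (lat_px - 60))
  if (cfg$step_offset != 0) {
    clim <- clim + cfg$step_offset * outer(post, step_px)
  }

  noise <- with_stream(cfg$seed, "temperature", {
    if (cfg$noise_sd == 0) {
      matrix(0, nt, npix)
    } else {
      innov <- matrix(
        rnorm(nt * npix, 0, cfg$noise_sd * sqrt(1 - cfg$ar1^2)), nt, npix
      )
      if (cfg$ar1 > 0) {
        apply(innov, 2, function(e) {
          as.numeric(stats::filter(e, cfg$ar1, method = "recursive"))
        })
      } else {
        innov
      }
    }
  })
  tmean <- clim + noise

  half <- with_stream(cfg$seed, "diurnal", {
    matrix(
      pmax(rnorm(nt * npix, cfg$diurnal_range / 2, cfg$diurnal_sd), 0),
      nt, npix
    )
  })
  tmax <- tmean + half
  tmin <- tmean - half
  tskin_min <- tmin - cfg$skin_offset
  if ((cfg$step_skin_offset %||% 0) != 0) {
    tskin_min <- tskin_min + cfg$step_skin_offset * outer(post, step_px)
  }

  dew <- with_stream(cfg$seed, "dewpoint", {
    tmean - matrix(
      pmax(rnorm(nt * npix, cfg$dewpoint_dep_mean, cfg$dewpoint_dep_sd), 0),
      nt, npix
    )
  })

  precip <- with_stream(cfg$seed, "precip", {
    wet <- matrix(runif(nt * npix) < cfg$wet_prob, nt, npix)
    amt <- matrix(
      rgamma(nt * npix, shape = cfg$precip_shape, scale = cfg$precip_scale),
      nt, npix
    )
    wet * amt
  })
  if (cfg$step_precip_factor != 1) {
    fac <- 1 + (cfg$step_precip_factor - 1) * outer(post, step_px)
    precip <- precip * fac
  }
  liquid <- precip * (tmean >= cfg$phase_split)
  solid <- precip - liquid

  # degree-day snowpack (water equivalent in mm, depth in m)
  swe <- matrix(0, nt, npix)
  state <- numeric(npix)
  for (t in seq_len(nt)) {
    state <- pmax(
      state + solid[t, ] - cfg$melt_factor * pmax(tmean[t, ], 0), 0
    )
    swe[t, ] <- state
  }
  snow_depth <- swe / cfg$snow_density * 0.1 # mm w.e. -> m depth

  wind <- with_stream(cfg$seed, "wind", {
    matrix(rweibull(nt * npix, cfg$wind_shape, cfg$wind_scale), nt, npix)
  })
  if (cfg$step_wind_offset != 0) {
    wind <- wind + cfg$step_wind_offset * outer(post, step_px)
  }

  # forced event days: warm, snow-covered, rainy
  if (!is.null(cfg$events) && nrow(cfg$events) > 0) {
    ev <- cfg$events
    ti <- match(
      paste(ev$year, ev$month, ev$day),
      paste(time$year, time$month, time$day)
    )
    if (anyNA(ti)) abort("event dates outside the simulated span.")
    px <- (ev$lon - 1L) * nlat + ev$lat
    idx <- cbind(ti, px)
    old_solid <- precip[idx] - liquid[idx]
    tmean[idx] <- 3
    tmax[idx] <- pmax(tmax[idx], 3)
    tmin[idx] <- pmin(tmin[idx], 3)
    tskin_min[idx] <- pmin(tskin_min[idx], 3 - cfg$skin_offset)
    dew[idx] <- pmin(dew[idx], 3)
    liquid[idx] <- 6
    precip[idx] <- old_solid + 6
    snow_depth[idx] <- pmax(snow_depth[idx], 0.2)
  }

  shape <- function(m) array(m, dim = c(nt, nlat, nlon))
  bioclim_weather(
    lat = lat, lon = lon, time = time,
    data = list(
      tmean = shape(tmean), tmin = shape(tmin), tmax = shape(tmax),
      tskin_min = shape(tskin_min), precip_total = shape(precip),
      precip_liquid = shape(liquid), snow_depth = shape(snow_depth),
      wind_max = shape(wind), dewpoint = shape(dew)
    ),
    land = matrix(TRUE, nlat, nlon),
    config = cfg
  )
}

#' Generate biome (taiga/tundra) and optional ice region masks
#'
#' Assigns every land pixel to exactly one biome. Tundra occupies the
#' northern part of the domain: pixels are ranked by latitude plus a
#' seeded jitter (which makes the boundary wiggly but spatially coherent)
#' and the top-ranked pixels are labelled tundra until the requested
#' area-weighted fraction is reached, so the realized fraction matches the
#' target to within one grid cell. An optional ice mask (excluded from the
#' land domain downstream, mirroring ice-sheet masking) is carved from the
#' top of the same ranking.
#'
#' @param lat,lon cell-centre coordinate vectors.
#' @param tundra_fraction target area-weighted tundra fraction in `[0, 1]`.
#' @param ice_fraction target area-weighted ice fraction in `[0, 1]`.
#' @param boundary_jitter latitude jitter (degrees) of the biome boundary.
#' @param seed integer seed.
#' @return An object of class `bioclim_masks`: list with `biome` (character
#'   matrix `[lat, lon]` of `"taiga"`/`"tundra"`), `ice` (logical matrix),
#'   and the coordinates.
#' @export
generate_region_masks <- function(lat, lon, tundra_fraction = 0.4,
                                  ice_fraction = 0, boundary_jitter = 1.5,
                                  seed = 1L) {
  check_number(tundra_fraction, "tundra_fraction", min = 0, max = 1)
  check_number(ice_fraction, "ice_fraction", min = 0, max = 1)
  nlat <- length(lat)
  nlon <- length(lon)
  areas <- cell_areas(lat, lon)
  score <- with_stream(seed, "masks", {
    matrix(rep(lat, times = nlon), nlat, nlon) +
      matrix(rnorm(nlat * nlon, 0, boundary_jitter), nlat, nlon)
  })
  ord <- order(score, decreasing = TRUE)
  cum <- cumsum(areas[ord])
  total <- sum(areas)
  pick_top <- function(frac) {
    sel <- matrix(FALSE, nlat, nlon)
    if (frac <= 0) return(sel)
    n <- findInterval(frac * total, cum) # largest m with cum[m] <= target
    if (n < length(cum) && frac >= 1) n <- length(cum)
    # include the boundary cell if that lands closer to the target
    if (n < length(cum) &&
        abs(cum[n + 1] - frac * total) < abs(frac * total - ifelse(n == 0, 0, cum[n]))) {
      n <- n + 1
    }
    sel[ord[seq_len(n)]] <- TRUE
    sel
  }
  ice <- pick_top(ice_fraction)
  tundra <- pick_top(ice_fraction + tundra_fraction) & !ice
  biome <- matrix("taiga", nlat, nlon)
  biome[tundra] <- "tundra"
  biome[ice] <- NA_character_
  structure(
    list(lat = lat, lon = lon, biome = biome, ice = ice),
    class = "bioclim_masks"
  )
}
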