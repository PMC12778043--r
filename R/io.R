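# Plain-text serialization of the gridded containers and grid utilities.
#
# A weather or indicator dataset is written as a directory holding
# `meta.json` (coordinates, calendar/years, units, land mask, config) and
# one CSV per variable with one row per time step and one column per grid
# cell (cells ordered latitude-fastest, matching R's column-major arrays).
# Everything is text, diffable, and reproducible byte-for-byte.

weather_units <- function() {
  c(
    tmean = "degC", tmin = "degC", tmax = "degC", tskin_min = "degC",
    precip_total = "mm/day", precip_liquid = "mm/day", snow_depth = "m",
    wind_max = "m/s", dewpoint = "degC"
  )
}

write_matrix_csv <- function(m, path) {
  df <- as.data.frame(m)
  names(df) <- sprintf("px%04d", seq_len(ncol(m)))
  readr::write_csv(df, path, progress = FALSE)
}

read_matrix_csv <- function(path) {
  as.matrix(readr::read_csv(path,
    show_col_types = FALSE, progress = FALSE
  ))
}

#' Write / read gridded daily weather (plain-text directory format)
#'
#' @param weather an [bioclim_weather()] object.
#' @param path directory to create/read.
#' @return `write_weather()` returns `path` invisibly; `read_weather()`
#'   returns a validated [bioclim_weather()] (all container invariants are
#'   re-checked on load).
#' @export
write_weather <- function(weather, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  meta <- list(
    kind = "bioclim_weather",
    lat = weather$lat, lon = weather$lon,
    years = range(weather$time$year),
    variables = names(weather$data),
    units = as.list(weather_units()[names(weather$data)]),
    land = as.vector(weather$land),
    config = weather$config[setdiff(
      names(weather$config), c("step_pixels", "events")
    )]
  )
  jsonlite::write_json(meta, file.path(path, "meta.json"),
    auto_unbox = TRUE, digits = NA
  )
  nt <- nrow(weather$time)
  for (v in names(weather$data)) {
    write_matrix_csv(
      matrix(weather$data[[v]], nrow = nt),
      file.path(path, paste0(v, ".csv"))
    )
  }
  invisible(path)
}

#' @rdname write_weather
#' @param rename optional named character vector mapping required variable
#'   names to the file names actually present (e.g.
#'   `c(tmean = "t2m_mean")`).
#' @export
read_weather <- function(path, rename = NULL) {
  meta <- read_meta(path, "bioclim_weather")
  lat <- as.numeric(meta$lat)
  lon <- as.numeric(meta$lon)
  time <- noleap_calendar(as.integer(meta$years))
  data <- lapply(bioclim_weather_vars(), function(v) {
    fname <- if (!is.null(rename) && v %in% names(rename)) rename[[v]] else v
    f <- file.path(path, paste0(fname, ".csv"))
    if (!file.exists(f)) {
      abort(sprintf("missing variable: %s", v),
        class = "bioclim_missing_variable"
      )
    }
    m <- read_matrix_csv(f)
    if (nrow(m) != nrow(time) || ncol(m) != length(lat) * length(lon)) {
      abort(sprintf("inconsistent dimensions in `%s`", v),
        class = "bioclim_bad_dimensions"
      )
    }
    array(m, dim = c(nrow(time), length(lat), length(lon)))
  })
  names(data) <- bioclim_weather_vars()
  bioclim_weather(
    lat = lat, lon = lon, time = time, data = data,
    land = matrix(as.logical(meta$land), length(lat), length(lon))
  )
}

read_meta <- function(path, kind) {
  f <- file.path(path, "meta.json")
  if (!file.exists(f)) abort(sprintf("no meta.json under `%s`.", path))
  meta <- jsonlite::read_json(f, simplifyVector = TRUE)
  if (!identical(meta$kind, kind)) {
    abort(sprintf("`%s` is not a %s dataset.", path, kind))
  }
  meta
}

#' Write / read an annual indicator cube (plain-text directory format)
#'
#' @param cube an [bioclim_cube()].
#' @param path directory to create/read.
#' @return `write_cube()` returns `path` invisibly; `read_cube()` a
#'   validated [bioclim_cube()].
#' @export
write_cube <- function(cube, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  meta <- list(
    kind = "bioclim_cube",
    lat = cube$lat, lon = cube$lon, years = cube$years,
    variables = names(cube$data),
    land = as.vector(cube$land),
    config = unclass(cube$config)
  )
  jsonlite::write_json(meta, file.path(path, "meta.json"),
    auto_unbox = TRUE, digits = NA
  )
  for (v in names(cube$data)) {
    write_matrix_csv(
      matrix(cube$data[[v]], nrow = length(cube$years)),
      file.path(path, paste0(v, ".csv"))
    )
  }
  invisible(path)
}

#' @rdname write_cube
#' @export
read_cube <- function(path) {
  meta <- read_meta(path, "bioclim_cube")
  lat <- as.numeric(meta$lat)
  lon <- as.numeric(meta$lon)
  years <- as.integer(meta$years)
  data <- lapply(bioclim_indicator_vars(), function(v) {
    f <- file.path(path, paste0(v, ".csv"))
    if (!file.exists(f)) {
      abort(sprintf("missing variable: %s", v),
        class = "bioclim_missing_variable"
      )
    }
    m <- read_matrix_csv(f)
    if (nrow(m) != length(years) || ncol(m) != length(lat) * length(lon)) {
      abort(sprintf("inconsistent dimensions in `%s`", v),
        class = "bioclim_bad_dimensions"
      )
    }
    array(m, dim = c(length(years), length(lat), length(lon)))
  })
  names(data) <- bioclim_indicator_vars()
  bioclim_cube(
    years = years, lat = lat, lon = lon, data = data,
    land = matrix(as.logical(meta$land), length(lat), length(lon))
  )
}

#' Nearest-neighbour resampling of a categorical raster
#'
#' Reassigns labels onto a target grid by nearest input cell centre; no new
#' labels are created. Used to align a biome raster with the indicator grid.
#'
#' @param values matrix `[lat, lon]` of labels on the source grid.
#' @param src_lat,src_lon source cell centres.
#' @param dst_lat,dst_lon target cell centres.
#' @return Matrix `[dst_lat, dst_lon]`.
#' @export
resample_categorical <- function(values, src_lat, src_lon, dst_lat, dst_lon) {
  if (max(dst_lat) < min(src_lat) || min(dst_lat) > max(src_lat) ||
      max(dst_lon) < min(src_lon) || min(dst_lon) > max(src_lon)) {
    abort("disjoint extents.", class = "bioclim_disjoint_extents")
  }
  nearest <- function(x, centers) {
    vapply(x, function(v) which.min(abs(centers - v)), integer(1))
  }
  ii <- nearest(dst_lat, src_lat)
  jj <- nearest(dst_lon, src_lon)
  values[ii, jj, drop = FALSE]
}
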