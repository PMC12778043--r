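test_that("generation is deterministic given config and seed", {
  w1 <- tiny_weather(seed = 11)
  w2 <- tiny_weather(seed = 11)
  expect_identical(w1$data, w2$data)
  w3 <- tiny_weather(seed = 12)
  expect_false(identical(w1$data$tmean, w3$data$tmean))
})

test_that("per-variable RNG streams are independent", {
  w1 <- tiny_weather(seed = 5)
  w2 <- generate_weather(tiny_config(seed = 5, wind_scale = 14))
  expect_identical(w1$data$tmean, w2$data$tmean)
  expect_identical(w1$data$precip_total, w2$data$precip_total)
  expect_false(identical(w1$data$wind_max, w2$data$wind_max))
})

test_that("degenerate config gives a constant temperature field", {
  w <- generate_weather(tiny_config(
    seasonal_amp = 0, noise_sd = 0, trend = 0
  ))
  for (j in seq_along(w$lon)) {
    for (i in seq_along(w$lat)) {
      expect_equal(diff(range(w$data$tmean[, i, j])), 0)
    }
  }
})

test_that("physical invariants hold at every cell", {
  w <- tiny_weather(seed = 3, years = c(1990, 1993))
  expect_true(all(w$data$tmin <= w$data$tmean))
  expect_true(all(w$data$tmean <= w$data$tmax))
  expect_true(all(w$data$precip_liquid >= 0))
  expect_true(all(w$data$precip_liquid <= w$data$precip_total + 1e-12))
  expect_true(all(w$data$snow_depth >= 0))
  expect_true(all(w$data$dewpoint <= w$data$tmean + 1e-12))
  # mass sanity: the solid part is exactly total minus liquid and splits
  # at the configured phase temperature
  solid <- w$data$precip_total - w$data$precip_liquid
  warm <- w$data$tmean >= w$config$phase_split
  expect_true(all(solid[warm] == 0))
  expect_true(all(w$data$precip_liquid[!warm] == 0))
})

test_that("snowpack melts away under sustained warmth without snowfall", {
  # warm constant climate, no seasonality: any early-winter snowpack at the
  # calendar start must be gone by mid-year and stay gone
  w <- generate_weather(tiny_config(
    temp_base = 10, temp_lapse = 0, seasonal_amp = 0, noise_sd = 0,
    years = c(2000, 2001)
  ))
  expect_true(all(w$data$snow_depth[300:730, , ] == 0))
})

test_that("an injected linear trend is recovered by least squares", {
  cfg <- weather_config(
    lat_range = c(60, 62), lon_range = c(20, 22), resolution = 1,
    years = c(1950, 2022), trend = 0.5, ar1 = 0, noise_sd = 1, seed = 21
  )
  w <- generate_weather(cfg)
  yrs <- sort(unique(w$time$year))
  for (i in 1:2) {
    ann <- vapply(
      yrs, function(y) mean(w$data$tmean[w$time$year == y, i, i]),
      numeric(1)
    )
    fit <- lsq_trend(ann, yrs)
    expect_lt(abs(fit$slope - 0.05), 3 * fit$std_error)
  }
})

test_that("region masks hit the requested area-weighted tundra fraction", {
  lat <- seq(60.5, 79.5, 1)
  lon <- seq(0.5, 39.5, 1)
  m0 <- generate_region_masks(lat, lon, tundra_fraction = 0)
  expect_true(all(m0$biome == "taiga"))
  m1 <- generate_region_masks(lat, lon, tundra_fraction = 1)
  expect_true(all(m1$biome == "tundra"))
  m <- generate_region_masks(lat, lon, tundra_fraction = 0.4, seed = 2)
  areas <- cell_areas(lat, lon)
  frac <- sum(areas[m$biome == "tundra"]) / sum(areas)
  expect_lt(abs(frac - 0.4), 0.05)
  expect_identical(
    m$biome, generate_region_masks(lat, lon, 0.4, seed = 2)$biome
  )
})

test_that("scenario presets modify the configuration as named", {
  base <- tiny_config()
  expect_equal(scenario_preset("stationary", base)$trend, 0)
  expect_equal(scenario_preset("warming", base, trend = 0.7)$trend, 0.7)
  expect_error(scenario_preset("banana", base))
})

test_that("step_change shifts the post-split mean by the offset", {
  cfg <- scenario_preset("step_change",
    tiny_config(nlat = 2, nlon = 2, years = c(1980, 2005), noise_sd = 2),
    split_year = 1993, offset = 2
  )
  w <- generate_weather(cfg)
  pre <- mean(w$data$tmean[w$time$year < 1993, 1, 1])
  post <- mean(w$data$tmean[w$time$year >= 1993, 1, 1])
  # noise tolerance: daily AR(1) noise averaged over ~13 years is tiny
  expect_lt(abs((post - pre) - 2), 0.3)
})

test_that("event injection creates rain only at the injected days", {
  cfg <- scenario_preset("event_injection",
    tiny_config(years = c(1990, 1999)),
    years = 1995:1997, lat = 2, lon = 3, n_per_year = 2
  )
  w <- generate_weather(cfg)
  liquid <- w$data$precip_liquid
  expect_equal(sum(liquid[, 2, 3] > 0), 6) # 3 years x 2 days
  liquid[, 2, 3] <- 0
  expect_true(all(liquid == 0))
  inj <- which(w$data$precip_liquid[, 2, 3] > 0)
  expect_true(all(w$data$snow_depth[inj, 2, 3] >= 0.01))
  expect_true(all(w$data$tmean[inj, 2, 3] >= 2))
})

test_that("invalid configurations are rejected", {
  expect_error(weather_config(resolution = 0), "resolution")
  expect_error(weather_config(ar1 = 1), "ar1")
  expect_error(weather_config(precip_scale = -1), "precip_scale")
  expect_error(weather_config(noise_sd = NaN), "noise_sd")
  expect_error(weather_config(years = c(2000, 1990)), "years")
})
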