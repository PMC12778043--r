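test_that("growing season is the longest qualifying run", {
  expect_equal(detect_growing_season(rep(10, 365))$length, 365)
  expect_equal(detect_growing_season(rep(-10, 365))$length, 0)
  # 20-day and 90-day warm spells: season must be the 90-day one
  tmean <- rep(-5, 365)
  tmean[50:69] <- 8
  tmean[120:209] <- 8
  gs <- detect_growing_season(tmean)
  expect_equal(gs$start, 120)
  expect_equal(gs$end, 209)
  expect_equal(gs$length, 90)
  # inclusive >= at the threshold
  expect_equal(detect_growing_season(rep(5, 365))$length, 365)
  expect_error(detect_growing_season(c(rep(5, 100), NA)), "gap")
})

test_that("degree-day sums follow the standard conventions", {
  expect_equal(degree_day_sum(c(6, 7, 8), 5, "above"), 6)
  expect_equal(degree_day_sum(rep(5, 10), 5, "above"), 0) # strict exceedance
  expect_equal(degree_day_sum(c(-10, -5, 2), 0, "below"), -15)
  expect_error(degree_day_sum(numeric(0)), "empty")
})

test_that("frost in growing season sums sub-zero skin minima", {
  none <- list(start = NA, end = NA, length = 0L)
  expect_equal(frost_in_growing_season(c(-1, 3, -0.5), none), 0)
  season <- list(start = 1L, end = 3L, length = 3L)
  expect_equal(frost_in_growing_season(c(-1, 3, -0.5), season), -1.5)
  expect_equal(frost_in_growing_season(c(1, 3, 0.5), season), 0)
})

test_that("snow-cover mask applies an inclusive depth threshold", {
  expect_false(any(snow_cover_mask(rep(0, 5))))
  expect_false(snow_cover_mask(0.009))
  expect_true(snow_cover_mask(0.01))
  expect_equal(snow_cover_mask(c(0, 0.5, 0, 0.5)), c(FALSE, TRUE, FALSE, TRUE))
  expect_error(snow_cover_mask(-0.1), "negative")
})

test_that("rain-on-snow counting is strict above 5 mm and needs snow", {
  expect_equal(count_ros(6, TRUE), 1)
  expect_equal(count_ros(5, TRUE), 0)
  expect_equal(count_ros(20, FALSE), 0)
  expect_error(count_ros(c(1, 2), TRUE), "misaligned")
})

test_that("winter warming events are inclusive at 2 C inside the window", {
  expect_equal(count_wwe(2.0, TRUE, TRUE), 1)
  expect_equal(count_wwe(5, TRUE, FALSE), 0) # outside Nov-Apr
  expect_equal(count_wwe(5, FALSE, TRUE), 0) # no snow
  expect_equal(count_wwe(1.99, TRUE, TRUE), 0)
})

test_that("summer warmth index sums strictly positive monthly means", {
  expect_equal(summer_warmth_index(rep(-3, 12)), 0)
  expect_equal(summer_warmth_index(c(5, 10, 8, rep(-2, 9))), 23)
  expect_equal(summer_warmth_index(c(0, rep(-1, 11))), 0) # strict > 0
})

test_that("snow season length is the longest continuous run", {
  expect_equal(snow_season_length(rep(FALSE, 365)), 0)
  m <- rep(FALSE, 30)
  m[3:5] <- TRUE
  m[10:14] <- TRUE
  expect_equal(snow_season_length(m), 5)
  expect_equal(snow_season_length(rep(TRUE, 365)), 365)
})

test_that("high-wind counting is strict above the threshold", {
  wind <- rep(7, 365)
  expect_equal(count_hwe(wind, quantile(wind, 0.9, names = FALSE)), 0)
  set.seed(1)
  wind <- rweibull(365 * 73, 2, 7)
  thr <- quantile(wind, 0.9, names = FALSE)
  counts <- vapply(
    split(wind, rep(1:73, each = 365)), count_hwe, numeric(1),
    threshold = thr
  )
  # ~10% of all days exceed their own 90th percentile (quantile
  # interpolation moves a handful of boundary days)
  expect_lt(abs(mean(counts) - 36.5), 0.5)
  expect_gt(count_hwe(wind[1:365] * 2, thr), 100)
})

test_that("magnitude index matches the hand-computed construction", {
  ref <- list(thresholds = rep(1, 365), q25 = 0, q75 = 2)
  base <- rep(0, 365)
  expect_equal(magnitude_index(base, 1:365, ref), 0)
  # two exceedance days: below the 3-day run rule
  x <- base
  x[180:181] <- 12
  expect_equal(magnitude_index(x, 1:365, ref), 0)
  # one 4-day event with normalized magnitudes 1,2,2,1 -> 6; a weaker
  # 3-day event of sum 3 is ignored (strongest event only)
  x <- base
  x[150:153] <- c(2, 4, 4, 2)
  x[200:202] <- c(2, 2, 2)
  expect_equal(magnitude_index(x, 1:365, ref), 6)
  # degenerate reference errors unless an epsilon is configured
  degen <- list(thresholds = rep(1, 365), q25 = 2, q75 = 2)
  expect_error(magnitude_index(x, 1:365, degen), class = "bioclim_degenerate_reference")
  expect_warning(v <- magnitude_index(x, 1:365, degen, eps = 2))
  expect_equal(v, sum(pmax((c(2, 4, 4, 2) - 2) / 2, 0)))
})

test_that("events outside the summer window are ignored", {
  ref <- list(thresholds = rep(1, 365), q25 = 0, q75 = 2)
  x <- rep(0, 365)
  x[10:14] <- 12 # January
  expect_equal(magnitude_index(x, 1:365, ref), 0)
  expect_gt(magnitude_index(replace(x, 180:184, 12), 1:365, ref), 0)
})

test_that("vapor pressure deficit is Magnus-consistent and non-negative", {
  expect_equal(vapor_pressure_deficit(20, 20), 0)
  vpd <- vapor_pressure_deficit(25, 15)
  # saturation pressure at 25 C ~ 3.17 kPa, at 15 C ~ 1.71 kPa
  expect_equal(vpd, 1.46, tolerance = 0.01)
  expect_true(all(vapor_pressure_deficit(c(0, 10), c(-5, 5)) > 0))
})

test_that("cube engine equals the naive per-pixel oracle", {
  w <- tiny_weather(nlat = 5, nlon = 5, years = c(1950, 1952), seed = 9)
  cfg <- indicator_config(reference_years = c(1950, 1952))
  cube <- compute_annual_indicators(w, cfg)
  cfg$reference_years <- c(1950, 1952)
  for (i in seq_along(w$lat)) {
    for (j in seq_along(w$lon)) {
      ora <- oracle_indicators_pixel(
        w$data$tmean[, i, j], w$data$tmax[, i, j],
        w$data$tskin_min[, i, j], w$data$precip_liquid[, i, j],
        w$data$snow_depth[, i, j], w$data$wind_max[, i, j],
        w$data$dewpoint[, i, j], w$time, cfg
      )
      for (v in c("GSL", "SSL", "ROS", "WWE", "HWE")) {
        expect_identical(
          as.numeric(cube$data[[v]][, i, j]), as.numeric(ora[, v])
        )
      }
      for (v in c("GDD", "FGS", "FDD", "SWI", "HWMI", "VPDI")) {
        expect_equal(cube$data[[v]][, i, j], unname(ora[, v]),
          tolerance = 1e-9
        )
      }
    }
  }
})

test_that("cube invariants and variable couplings hold on generated data", {
  w <- tiny_weather(nlat = 4, nlon = 4, years = c(1960, 1964), seed = 17)
  cube <- compute_annual_indicators(
    w, indicator_config(reference_years = c(1960, 1964))
  )
  expect_true(all(cube$data$GSL >= 0 & cube$data$GSL <= 365, na.rm = TRUE))
  expect_true(all(cube$data$ROS == round(cube$data$ROS), na.rm = TRUE))
  expect_true(all(cube$data$FDD <= 0, na.rm = TRUE))
  expect_true(all(cube$data$FGS <= 0, na.rm = TRUE))
  # GSL = 0 <=> GDD = 0 and FGS = 0
  z <- cube$data$GSL == 0
  expect_true(all(cube$data$GDD[z] == 0, na.rm = TRUE))
  expect_true(all(cube$data$FGS[z] == 0, na.rm = TRUE))
  # hydrological-year variables missing only in the first year
  expect_true(all(is.na(cube$data$SSL[1, , ])))
  expect_false(anyNA(cube$data$SSL[-1, , ]))
  # SSL bounded by the number of snow-covered days in its hydrological year
  for (k in 2:5) {
    hy <- (w$time$year == cube$years[k] - 1 & w$time$month >= 7) |
      (w$time$year == cube$years[k] & w$time$month < 7)
    for (i in 1:4) {
      covered <- sum(w$data$snow_depth[hy, i, i] >= 0.01)
      expect_lte(cube$data$SSL[k, i, i], covered)
    }
  }
})

test_that("masked pixels come out missing, never zero", {
  w <- tiny_weather(nlat = 3, nlon = 3)
  w$land[2, 2] <- FALSE
  cube <- compute_annual_indicators(
    w, indicator_config(reference_years = c(1950, 1952))
  )
  expect_true(all(is.na(cube$data$GDD[, 2, 2])))
  expect_false(anyNA(cube$data$GDD[, 1, 1]))
})

test_that("indicator responses are monotone in thresholds and warming", {
  w <- tiny_weather(nlat = 3, nlon = 3, years = c(1955, 1958), seed = 23)
  cfg <- indicator_config(reference_years = c(1955, 1958))
  cube <- compute_annual_indicators(w, cfg)
  # raising the ROS precipitation threshold never increases counts
  cfg10 <- indicator_config(
    ros_threshold = 10, reference_years = c(1955, 1958)
  )
  cube10 <- compute_annual_indicators(w, cfg10)
  expect_true(all(cube10$data$ROS <= cube$data$ROS, na.rm = TRUE))
  # uniform +1 C warming never decreases GDD/SWI, never deepens FDD
  warm <- w
  for (v in c("tmean", "tmin", "tmax")) warm$data[[v]] <- warm$data[[v]] + 1
  cubew <- compute_annual_indicators(warm, cfg)
  expect_true(all(cubew$data$GDD >= cube$data$GDD - 1e-9, na.rm = TRUE))
  expect_true(all(cubew$data$SWI >= cube$data$SWI - 1e-9, na.rm = TRUE))
  expect_true(all(abs(cubew$data$FDD) <= abs(cube$data$FDD) + 1e-9,
    na.rm = TRUE
  ))
})

test_that("single-pixel cube equals direct per-series kernel calls", {
  tm <- rep(-5, 365)
  tm[150:250] <- 10
  w <- manual_weather(tm, wind_max = rep(5, 365))
  # a 1-year reference period has degenerate annual-maxima quartiles, so
  # the configured epsilon kicks in (with its warning)
  cube <- suppressWarnings(compute_annual_indicators(
    w, indicator_config(reference_years = c(2000, 2000), magnitude_eps = 1)
  ))
  gs <- detect_growing_season(tm)
  expect_equal(cube$data$GSL[1, 1, 1], gs$length)
  expect_equal(
    cube$data$GDD[1, 1, 1],
    degree_day_sum(tm[gs$start:gs$end], 5, "above")
  )
  mm <- vapply(1:12, function(m) {
    mean(tm[noleap_calendar(c(2000, 2000))$month == m])
  }, numeric(1))
  expect_equal(cube$data$SWI[1, 1, 1], summer_warmth_index(mm))
  expect_equal(cube$data$HWE[1, 1, 1], 0) # constant wind, strict >
})
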