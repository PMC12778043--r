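test_that("Sen's slope equals the brute-force pairwise median", {
  expect_equal(sen_slope(c(1, 2, 4), c(0, 1, 2)), 1.5)
  expect_equal(sen_slope(rep(3, 10)), 0)
  set.seed(101)
  for (rep in 1:50) {
    n <- sample(3:60, 1)
    v <- rnorm(n) + runif(1, -0.5, 0.5) * seq_len(n)
    expect_identical(sen_slope(v), oracle_sen_slope(v))
  }
  expect_error(sen_slope(1), "2 valid")
  expect_error(sen_slope(c(1, 2), c(5, 5)), "timestamps")
})

test_that("Sen's slope is equivariant under adding a linear ramp", {
  set.seed(7)
  v <- rnorm(40)
  t <- seq_len(40)
  expect_equal(sen_slope(v + 0.3 * t, t), sen_slope(v, t) + 0.3,
    tolerance = 1e-12
  )
})

test_that("Mann-Kendall matches enumeration and handles ties", {
  mk <- mann_kendall(c(1, 2, 3, 4), method = "exact")
  expect_equal(mk$s, 6)
  expect_equal(mk$p, 2 / 24)
  expect_equal(mk$p, oracle_mk_exact_p(c(1, 2, 3, 4)))
  # antisymmetry: reversal flips S, keeps p
  set.seed(3)
  v <- rnorm(15)
  a <- mann_kendall(v)
  b <- mann_kendall(rev(v))
  expect_equal(a$s, -b$s)
  expect_equal(a$p, b$p)
  # all tied: S = 0, p = 1 under tie-corrected variance
  tied <- mann_kendall(rep(2, 8))
  expect_equal(tied$s, 0)
  expect_equal(tied$p, 1)
  expect_error(mann_kendall(c(1, 2)), "3 valid")
  expect_error(mann_kendall(1:8, method = "exact"), "n <= 7")
})

test_that("normal approximation is close to exact enumeration at n = 7", {
  for (v in list(1:7, c(1, 3, 2, 4, 6, 5, 7), c(2, 1, 4, 3, 6, 5, 7))) {
    p_norm <- mann_kendall(v)$p
    p_exact <- mann_kendall(v, method = "exact")$p
    expect_lt(abs(p_norm - p_exact), 0.02)
  }
})

test_that("S statistic agrees with the naive loop on fuzzed series", {
  set.seed(11)
  for (rep in 1:25) {
    v <- sample(1:6, sample(5:30, 1), replace = TRUE) # many ties
    expect_equal(mann_kendall(v)$s, oracle_mk_s(v))
  }
})

test_that("least-squares trend recovers exact and noisy lines", {
  x <- 0:10
  fit <- suppressWarnings(lsq_trend(2 * x + 1, x)) # perfect-fit warning
  expect_equal(fit$slope, 2)
  expect_equal(fit$intercept, 1)
  const <- lsq_trend(rep(4, 10))
  expect_equal(const$slope, 0, tolerance = 1e-12)
  expect_gt(const$p_value, 0.99)
  set.seed(5)
  y <- 0.3 * (1:73) + rnorm(73, 0, 2)
  fit <- lsq_trend(y, 1:73)
  expect_lt(abs(fit$slope - 0.3), 3 * fit$std_error)
  expect_error(lsq_trend(c(1, 2, 3), rep(1, 3)), "degenerate")
})

test_that("single-pixel trend map equals direct series calls", {
  set.seed(13)
  v <- cumsum(rnorm(20))
  cube <- manual_cube("SWI", array(pmax(v, 0), c(20, 1, 1)),
    years = 2001:2020
  )
  tm <- trend_map(cube, "SWI", per_decade = FALSE)
  expect_equal(tm$slope, sen_slope(pmax(v, 0), 2001:2020))
  expect_equal(tm$p_value, mann_kendall(pmax(v, 0))$p)
  tm10 <- trend_map(cube, "SWI", per_decade = TRUE)
  expect_equal(tm10$slope, 10 * tm$slope)
  expect_error(trend_map(cube, "NOPE"), "unknown variable")
})

test_that("pixel-wise MK keeps its nominal size on stationary fields", {
  set.seed(29)
  vals <- array(rnorm(40 * 10 * 10), c(40, 10, 10))
  cube <- manual_cube("SWI", abs(vals))
  tm <- trend_map(cube, "SWI")
  # 100 independent pixels at alpha = 0.05: well under 10% significant
  expect_lte(mean(tm$significant), 0.10)
})

test_that("anomaly series are zero-mean over the baseline", {
  cube <- manual_cube("SWI", array(7, c(10, 3, 3)), years = 1951:1960)
  an <- region_anomaly_series(cube,
    matrix(TRUE, 3, 3), "SWI",
    baseline = c(1951, 1955), smooth = 5
  )
  expect_true(all(an$anomaly == 0))
  set.seed(31)
  cube <- manual_cube("SWI", array(abs(rnorm(10 * 9, 10)), c(10, 3, 3)),
    years = 1951:1960
  )
  an <- region_anomaly_series(cube, matrix(TRUE, 3, 3), "SWI",
    baseline = c(1951, 1955), smooth = 1
  )
  expect_equal(mean(an$anomaly[an$year <= 1955]), 0, tolerance = 1e-9)
})

test_that("moving-average smoothing shrinks its window at the edges", {
  x <- c(1, 2, 3, 4, 5)
  sm <- moving_average_ref <- function(x) {
    # expected: mean over the symmetric window clipped to the series
    c(mean(x[1:3]), mean(x[1:4]), mean(x[1:5]), mean(x[2:5]), mean(x[3:5]))
  }
  an <- region_anomaly_series(
    manual_cube("SWI", array(rep(x, each = 1), c(5, 1, 1)),
      years = 2001:2005
    ),
    matrix(TRUE, 1, 1), "SWI",
    baseline = c(2001, 2005), smooth = 5
  )
  expect_equal(an$smoothed, moving_average_ref(x) - mean(x))
})

test_that("disjoint regions combine area-weighted to the domain mean", {
  set.seed(37)
  vals <- abs(array(rnorm(8 * 4 * 4, 10), c(8, 4, 4)))
  cube <- manual_cube("SWI", vals, years = 1993:2000)
  regions <- matrix(c("a", "b"), 4, 4) # split the domain
  pair <- region_trend_pair(cube, regions, "SWI",
    periods = list(full = c(1993, 2000))
  )
  whole <- region_trend_pair(cube, matrix(TRUE, 4, 4), "SWI",
    periods = list(full = c(1993, 2000))
  )
  areas <- cell_areas(cube$lat, cube$lon)
  wa <- sum(areas[regions == "a"])
  wb <- sum(areas[regions == "b"])
  combined <- (pair$mean_slope[pair$region == "a"] * wa +
    pair$mean_slope[pair$region == "b"] * wb) / (wa + wb)
  expect_equal(combined, whole$mean_slope, tolerance = 1e-9)
  # one-pixel region: mean is that pixel's slope, degenerate interval
  one <- matrix(NA, 4, 4)
  one[2, 2] <- "px"
  p1 <- region_trend_pair(cube, one, "SWI",
    periods = list(full = c(1993, 2000))
  )
  tm <- trend_map(cube, "SWI", per_decade = FALSE)
  px_slope <- tm$slope[tm$lat == cube$lat[2] & tm$lon == cube$lon[2]]
  expect_equal(p1$mean_slope, px_slope)
  expect_equal(p1$q05, p1$q95)
})
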