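# Nonparametric and least-squares trend estimators used for the pixel-wise
# and regional analyses.

#' Sen's slope estimator
#'
#' Median of all pairwise slopes `(v_j - v_i) / (t_j - t_i)`, `i < j`; a
#' robust nonparametric trend estimate. Missing values are dropped pairwise.
#'
#' @param value series values.
#' @param year time coordinate (defaults to `1..n`).
#' @return Slope in value units per year.
#' @export
sen_slope <- function(value, year = seq_along(value)) {
  ok <- is.finite(value) & is.finite(year)
  v <- value[ok]
  t <- year[ok]
  if (length(v) < 2L) abort("need at least 2 valid points.")
  if (length(unique(t)) < 2L) abort("all timestamps equal.")
  dv <- outer(v, v, "-")
  dt <- outer(t, t, "-")
  keep <- upper.tri(dt) & dt != 0
  median(dv[keep] / dt[keep])
}

#' Mann-Kendall trend test
#'
#' Computes the S statistic `sum_{i<j} sign(v_j - v_i)`, its tie-corrected
#' variance, the continuity-corrected normal deviate Z, and the two-sided
#' p-value. For short series (`n <= 7`) an exact mode enumerates all
#' permutations of the observed values and returns
#' `P(|S_perm| >= |S_obs|)`.
#'
#' @param value series values (missing values dropped).
#' @param method `"normal"` (default) or `"exact"` (only for `n <= 7`).
#' @return `list(s, var_s, z, p, n)`.
#' @export
mann_kendall <- function(value, method = c("normal", "exact")) {
  method <- match.arg(method)
  v <- value[is.finite(value)]
  n <- length(v)
  if (n < 3L) abort("need at least 3 valid points.")
  # m[i, j] = sign(v_j - v_i); S sums the upper triangle (i < j)
  sgn <- sign(outer(v, v, function(a, b) b - a))
  s <- sum(sgn[upper.tri(sgn)])
  ties <- table(v)
  ties <- ties[ties > 1]
  var_s <- (n * (n - 1) * (2 * n + 5) -
    sum(ties * (ties - 1) * (2 * ties + 5))) / 18
  if (method == "exact") {
    if (n > 7L) abort("exact mode only for n <= 7.")
    perms <- permutations_of(n)
    s_perm <- apply(perms, 1, function(p) {
      m <- sign(outer(v[p], v[p], function(a, b) b - a))
      sum(m[upper.tri(m)])
    })
    p <- mean(abs(s_perm) >= abs(s))
    z <- NA_real_
  } else {
    z <- if (var_s == 0) {
      0
    } else if (s > 0) {
      (s - 1) / sqrt(var_s)
    } else if (s < 0) {
      (s + 1) / sqrt(var_s)
    } else {
      0
    }
    p <- 2 * pnorm(-abs(z))
  }
  list(s = s, var_s = var_s, z = z, p = p, n = n)
}

# all permutations of 1..n as an (n! x n) matrix
permutations_of <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- permutations_of(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, ifelse(sub >= k, sub + 1L, sub))
  }))
}

#' Ordinary least-squares trend
#'
#' Simple linear regression of a series on time with a t-test on the slope;
#' used for fractional-area trends.
#'
#' @param value series values.
#' @param year time coordinate.
#' @return One-row tibble: `slope`, `intercept`, `std_error`, `p_value`,
#'   `r_squared`, `n`.
#' @export
lsq_trend <- function(value, year = seq_along(value)) {
  ok <- is.finite(value) & is.finite(year)
  if (sum(ok) < 3L) abort("need at least 3 valid points.")
  if (length(unique(year[ok])) < 2L) abort("degenerate time coordinate.")
  if (var(value[ok]) == 0) { # flat series: no trend, nothing to test
    return(tibble(
      slope = 0, intercept = value[ok][1], std_error = 0,
      p_value = 1, r_squared = 0, n = sum(ok)
    ))
  }
  fit <- lm(value[ok] ~ year[ok])
  sm <- summary(fit)
  co <- sm$coefficients
  tibble(
    slope = co[2, 1], intercept = co[1, 1], std_error = co[2, 2],
    p_value = co[2, 4], r_squared = sm$r.squared, n = sum(ok)
  )
}

#' Pixel-wise Sen's slope and Mann-Kendall trend map
#'
#' Applies [sen_slope()] and [mann_kendall()] to every land pixel's annual
#' series of one indicator over a period. Pixels with fewer than 3 valid
#' years get missing results.
#'
#' @param cube an [bioclim_cube()].
#' @param variable indicator name.
#' @param period `c(first, last)` year range, default the full span.
#' @param per_decade if `TRUE` (default) slopes are reported per decade.
#' @param alpha significance level of the Mann-Kendall mask.
#' @return A tibble of class `bioclim_trend` with columns `lat`, `lon`,
#'   `slope`, `s`, `z`, `p_value`, `significant`; attributes record the
#'   variable, period, units and alpha.
#' @export
trend_map <- function(cube, variable, period = NULL, per_decade = TRUE,
                      alpha = 0.05) {
  arr <- cube_variable(cube, variable)
  period <- period %||% range(cube$years)
  check_period(period, cube$years)
  sel <- cube$years >= period[1] & cube$years <= period[2]
  yrs <- cube$years[sel]
  grid <- expand.grid(
    i = seq_along(cube$lat), j = seq_along(cube$lon)
  )
  rows <- purrr::pmap_dfr(grid, function(i, j) {
    if (!cube$land[i, j]) {
      return(tibble(
        lat = cube$lat[i], lon = cube$lon[j], slope = NA_real_,
        s = NA_real_, z = NA_real_, p_value = NA_real_, significant = NA
      ))
    }
    v <- arr[sel, i, j]
    if (sum(is.finite(v)) < 3L) {
      return(tibble(
        lat = cube$lat[i], lon = cube$lon[j], slope = NA_real_,
        s = NA_real_, z = NA_real_, p_value = NA_real_, significant = NA
      ))
    }
    sl <- sen_slope(v, yrs)
    mk <- mann_kendall(v)
    tibble(
      lat = cube$lat[i], lon = cube$lon[j],
      slope = if (per_decade) sl * 10 else sl,
      s = mk$s, z = mk$z, p_value = mk$p,
      significant = mk$p <= alpha
    )
  })
  structure(rows,
    class = c("bioclim_trend", class(rows)),
    variable = variable, period = period,
    units = if (per_decade) "per decade" else "per year", alpha = alpha
  )
}

cube_variable <- function(cube, variable) {
  if (!variable %in% names(cube$data)) {
    abort(sprintf("unknown variable `%s`.", variable))
  }
  cube$data[[variable]]
}

#' @export
tidy.bioclim_trend <- function(x, ...) as_tibble(x)

#' @export
glance.bioclim_trend <- function(x, ...) {
  ok <- !is.na(x$slope)
  tibble(
    variable = attr(x, "variable"),
    period_start = attr(x, "period")[1], period_end = attr(x, "period")[2],
    n_pixels = sum(ok),
    mean_slope = mean(x$slope[ok]),
    frac_significant = mean(x$significant[ok]),
    frac_positive = mean(x$slope[ok] > 0)
  )
}

#' Region-averaged anomaly series
#'
#' Area-weighted (or plain) annual mean of one indicator over the pixels of
#' each region, expressed as anomalies to the mean of a baseline period and
#' optionally smoothed with a centred moving average whose window shrinks at
#' the series ends.
#'
#' @param cube an [bioclim_cube()].
#' @param regions logical matrix `[lat, lon]` (one region) or a matrix of
#'   region labels (integer/character; `NA` = outside).
#' @param variable indicator name.
#' @param baseline `c(first, last)` baseline years (default 1951-1980
#'   clipped to the span).
#' @param smooth moving-average window in years (default 5; 1 disables).
#' @param weighted area-weight the spatial mean (default `TRUE`).
#' @return Tibble of class `bioclim_anomaly`: `region`, `year`, `anomaly`,
#'   `smoothed`.
#' @export
region_anomaly_series <- function(cube, regions, variable,
                                  baseline = c(1951, 1980), smooth = 5,
                                  weighted = TRUE) {
  arr <- cube_variable(cube, variable)
  check_period(baseline, cube$years, "baseline")
  labels <- region_labels(regions, cube)
  w <- cell_areas(cube$lat, cube$lon)
  if (!weighted) w[] <- 1
  purrr::map_dfr(unique(na.omit(as.vector(labels))), function(lab) {
    px <- which(labels == lab & cube$land)
    if (!length(px)) abort("empty region.")
    series <- vapply(seq_along(cube$years), function(k) {
      v <- arr[k, , ][px]
      ok <- is.finite(v)
      if (!any(ok)) return(NA_real_)
      sum(v[ok] * w[px][ok]) / sum(w[px][ok])
    }, numeric(1))
    base <- mean(
      series[cube$years >= baseline[1] & cube$years <= baseline[2]],
      na.rm = TRUE
    )
    anom <- series - base
    tibble(
      region = lab, year = cube$years, anomaly = anom,
      smoothed = moving_average(anom, smooth)
    )
  }) -> out
  structure(out,
    class = c("bioclim_anomaly", class(out)),
    variable = variable, baseline = baseline, smooth = smooth
  )
}

region_labels <- function(regions, cube) {
  if (is.logical(regions)) {
    labels <- matrix(NA_character_, length(cube$lat), length(cube$lon))
    labels[regions] <- "region"
    labels
  } else {
    regions
  }
}

#' Regional mean Sen slopes over two periods
#'
#' For each region and period, the (optionally area-weighted) mean of the
#' pixel Sen slopes together with the 5th-95th percentile range across
#' pixels — the per-region bars of the long-term versus recent trend
#' comparison.
#'
#' @param cube an [bioclim_cube()].
#' @param regions region label matrix (or logical mask).
#' @param variable indicator name.
#' @param periods named list of `c(first, last)` ranges; default the full
#'   span and the last 30 years.
#' @param weighted area-weight the regional mean slope (default `TRUE`).
#' @param per_decade report slopes per decade (default `FALSE`, i.e. per
#'   year).
#' @return Tibble: `region`, `period`, `first_year`, `last_year`,
#'   `mean_slope`, `q05`, `q95`, `n_pixels`.
#' @export
region_trend_pair <- function(cube, regions, variable, periods = NULL,
                              weighted = TRUE, per_decade = FALSE) {
  if (is.null(periods)) {
    full <- range(cube$years)
    periods <- list(
      full = full, recent = c(max(full[1], full[2] - 29L), full[2])
    )
  }
  labels <- region_labels(regions, cube)
  w <- cell_areas(cube$lat, cube$lon)
  if (!weighted) w[] <- 1
  purrr::imap_dfr(periods, function(pr, pname) {
    tm <- trend_map(cube, variable, pr, per_decade = per_decade)
    sl <- matrix(tm$slope, length(cube$lat), length(cube$lon))
    purrr::map_dfr(unique(na.omit(as.vector(labels))), function(lab) {
      px <- which(labels == lab & cube$land)
      if (!length(px)) abort("empty region.")
      s <- sl[px]
      ok <- is.finite(s)
      q <- quantile(s[ok], c(0.05, 0.95), names = FALSE)
      tibble(
        region = lab, period = pname,
        first_year = pr[1], last_year = pr[2],
        mean_slope = sum(s[ok] * w[px][ok]) / sum(w[px][ok]),
        q05 = q[1], q95 = q[2], n_pixels = sum(ok)
      )
    })
  })
}
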