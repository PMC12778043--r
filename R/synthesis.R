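# Bivariate synthesis of significant change in seasonally integrated versus
# event-related indicators between two 30-year windows.

#' Pixel-wise two-period change test for one indicator
#'
#' Welch's two-sided t-test (by default; set `var_equal = TRUE` for the
#' pooled-variance variant) comparing a pixel's annual values between two
#' non-overlapping periods, with the p-value recoded to 1 when
#' `p <= alpha` and 0 otherwise. Pixels with fewer than 2 valid years on
#' either side are missing. When both samples have zero variance the test
#' statistic is undefined: the p-value is set to 1 when the means are equal
#' (no change) and 0 when they differ (a deterministic shift).
#'
#' @param cube an [bioclim_cube()].
#' @param variable indicator name.
#' @param period1,period2 `c(first, last)` year ranges (default 1950-1979
#'   and 1993-2022).
#' @param var_equal use the pooled-variance t-test instead of Welch.
#' @param alpha recode threshold (default 0.05).
#' @return Tibble of class `bioclim_change`: `lat`, `lon`, `statistic`,
#'   `p_value`, `significant` (0/1/NA); attribute `variable`.
#' @export
period_change_test <- function(cube, variable, period1 = c(1950, 1979),
                               period2 = c(1993, 2022), var_equal = FALSE,
                               alpha = 0.05) {
  check_period(period1, cube$years, "period1")
  check_period(period2, cube$years, "period2")
  arr <- cube_variable(cube, variable)
  s1 <- cube$years >= period1[1] & cube$years <= period1[2]
  s2 <- cube$years >= period2[1] & cube$years <= period2[2]
  nlat <- length(cube$lat)
  nlon <- length(cube$lon)
  # vectorized Welch / pooled t-test over pixels
  x1 <- matrix(arr[s1, , ], nrow = sum(s1))
  x2 <- matrix(arr[s2, , ], nrow = sum(s2))
  n1 <- colSums(is.finite(x1))
  n2 <- colSums(is.finite(x2))
  m1 <- colMeans(x1, na.rm = TRUE)
  m2 <- colMeans(x2, na.rm = TRUE)
  v1 <- apply(x1, 2, var, na.rm = TRUE)
  v2 <- apply(x2, 2, var, na.rm = TRUE)
  if (var_equal) {
    sp <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  stat <- (m2 - m1) / se
  p <- 2 * pt(-abs(stat), df)
  zero_var <- is.finite(m1) & is.finite(m2) & se == 0
  p[zero_var & m1 == m2] <- 1
  p[zero_var & m1 != m2] <- 0
  stat[zero_var] <- NA_real_
  bad <- n1 < 2 | n2 < 2 | !as.vector(cube$land)
  p[bad] <- NA_real_
  stat[bad] <- NA_real_
  out <- tibble(
    lat = rep(cube$lat, times = nlon),
    lon = rep(cube$lon, each = nlat),
    statistic = stat, p_value = p,
    significant = ifelse(is.na(p), NA_integer_, as.integer(p <= alpha))
  )
  structure(out,
    class = c("bioclim_change", class(out)),
    variable = variable, period1 = period1, period2 = period2, alpha = alpha
  )
}

#' Default variable sets of the bivariate synthesis
#' @name synthesis_sets
#' @return Character vectors of indicator names.
#' @export
seasonal_variables <- function() c("GDD", "FDD", "SSL", "SWI")

#' @rdname synthesis_sets
#' @export
event_variables <- function() {
  c("FGS", "ROS", "WWE", "HWMI", "VPDI", "HWE")
}

#' Bivariate synthesis map of significant change
#'
#' Combines per-variable change tests into, per pixel, the proportion of
#' significant changes among the seasonally integrated set (GDD, FDD, SSL,
#' SWI; denominator 4) and among the event-related set (FGS, ROS, WWE,
#' HWMI, VPDI, HWE; denominator 6), a bivariate colour built from two
#' orthogonal ramps, and a contour mask of pixels where both proportions
#' reach at least 0.5.
#'
#' @param tests named list of [period_change_test()] results covering all
#'   ten variables on one grid.
#' @param seasonal,event variable-name sets (defaults above).
#' @return Tibble of class `bioclim_synthesis`: `lat`, `lon`,
#'   `seasonal_prop`, `event_prop`, `colour`, `contour`.
#' @export
synthesis_map <- function(tests, seasonal = seasonal_variables(),
                          event = event_variables()) {
  have <- vapply(tests, function(t) attr(t, "variable"), character(1))
  names(tests) <- have
  missing_layer <- setdiff(c(seasonal, event), have)
  if (length(missing_layer)) {
    abort(sprintf(
      "missing layer: %s", paste(missing_layer, collapse = ", ")
    ), class = "bioclim_missing_variable")
  }
  ref <- tests[[1]]
  prop_of <- function(vars) {
    mats <- lapply(tests[vars], function(t) t$significant)
    rowMeans(do.call(cbind, mats))
  }
  seasonal_prop <- prop_of(seasonal)
  event_prop <- prop_of(event)
  colour <- ifelse(
    is.na(seasonal_prop) | is.na(event_prop), NA_character_,
    grDevices::rgb(seasonal_prop, 1 - (seasonal_prop + event_prop) / 2,
      event_prop
    )
  )
  out <- tibble(
    lat = ref$lat, lon = ref$lon,
    seasonal_prop = seasonal_prop, event_prop = event_prop,
    colour = colour,
    contour = seasonal_prop >= 0.5 & event_prop >= 0.5
  )
  structure(out,
    class = c("bioclim_synthesis", class(out)),
    seasonal = seasonal, event = event
  )
}
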