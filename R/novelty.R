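# Newly emerging and disappearing extreme-event regimes between two
# 30-year windows.

#' Novel and disappearing event areas between two periods
#'
#' Classifies each land pixel by whether an event rule was satisfied in any
#' year of the baseline window and/or the modern window: `"new"` (never in
#' the baseline, at least once in the modern window), `"past"` (the
#' reverse), `"both"`, `"neither"`, or `"masked"` (off-land or missing data
#' in either window). Proportional coverages of `"new"` and `"past"` are
#' area-weighted over the valid land domain.
#'
#' @param cube an [bioclim_cube()].
#' @param rule an [event_rule()].
#' @param baseline,modern `c(first, last)` year ranges; must not overlap.
#' @return An object of class `bioclim_novelty`: `category` matrix
#'   `[lat, lon]`, `summary` tibble with area-weighted proportions, the
#'   rule and the two periods.
#' @export
novelty_mask <- function(cube, rule, baseline = c(1950, 1979),
                         modern = c(1993, 2022)) {
  check_period(baseline, cube$years, "baseline")
  check_period(modern, cube$years, "modern")
  if (max(baseline[1], modern[1]) <= min(baseline[2], modern[2])) {
    abort("baseline and modern periods overlap.",
      class = "bioclim_overlapping_periods"
    )
  }
  arr <- cube_variable(cube, rule$variable)
  count_hits <- function(period) {
    sel <- which(cube$years >= period[1] & cube$years <= period[2])
    hits <- matrix(0L, length(cube$lat), length(cube$lon))
    valid <- matrix(0L, length(cube$lat), length(cube$lon))
    for (k in sel) {
      slice <- arr[k, , ]
      h <- rule_holds(rule, slice)
      hits <- hits + ifelse(is.na(h), 0L, h)
      valid <- valid + !is.na(slice)
    }
    list(hits = hits, valid = valid)
  }
  b <- count_hits(baseline)
  m <- count_hits(modern)
  ok <- cube$land & b$valid > 0 & m$valid > 0
  category <- matrix("masked", length(cube$lat), length(cube$lon))
  category[ok & b$hits == 0 & m$hits > 0] <- "new"
  category[ok & b$hits > 0 & m$hits == 0] <- "past"
  category[ok & b$hits > 0 & m$hits > 0] <- "both"
  category[ok & b$hits == 0 & m$hits == 0] <- "neither"
  areas <- cell_areas(cube$lat, cube$lon)
  denom <- sum(areas[ok])
  cat_area <- vapply(
    c("new", "past", "both", "neither"),
    function(cc) sum(areas[category == cc]), numeric(1), USE.NAMES = FALSE
  )
  summary <- tibble(
    category = c("new", "past", "both", "neither"),
    area_km2 = cat_area,
    proportion = cat_area / denom
  )
  structure(
    list(
      category = category, summary = summary, rule = rule,
      baseline = baseline, modern = modern,
      lat = cube$lat, lon = cube$lon
    ),
    class = "bioclim_novelty"
  )
}

#' @export
print.bioclim_novelty <- function(x, ...) {
  cat(sprintf(
    "<bioclim_novelty> %s: new %.1f%%, past %.1f%% (baseline %d-%d vs %d-%d)\n",
    x$rule$variable,
    100 * x$summary$proportion[x$summary$category == "new"],
    100 * x$summary$proportion[x$summary$category == "past"],
    x$baseline[1], x$baseline[2], x$modern[1], x$modern[2]
  ))
  invisible(x)
}

#' @export
tidy.bioclim_novelty <- function(x, ...) {
  tibble(
    lat = rep(x$lat, times = length(x$lon)),
    lon = rep(x$lon, each = length(x$lat)),
    category = as.vector(x$category)
  )
}

#' Overlap of newly emerged event areas across rules
#'
#' Pixel-wise count of how many rules flag a pixel `"new"`, plus the
#' area-weighted proportion of land covered by at least one rule's new
#' area (the union).
#'
#' @param masks list of [novelty_mask()] results on a shared grid.
#' @return An object of class `bioclim_overlap`: `count` matrix, tibble
#'   `summary` (per-count proportions), and `union_proportion`.
#' @export
overlap_count <- function(masks) {
  if (!length(masks)) abort("need at least one mask.")
  ref <- masks[[1]]
  for (m in masks[-1]) {
    if (!identical(m$lat, ref$lat) || !identical(m$lon, ref$lon)) {
      abort("masks are on different grids.", class = "bioclim_grid_mismatch")
    }
  }
  count <- Reduce(
    `+`, lapply(masks, function(m) (m$category == "new") * 1L)
  )
  valid <- Reduce(
    `|`, lapply(masks, function(m) m$category != "masked")
  )
  areas <- cell_areas(ref$lat, ref$lon)
  denom <- sum(areas[valid])
  union_prop <- sum(areas[count >= 1]) / denom
  summary <- purrr::map_dfr(seq(0, length(masks)), function(kk) {
    tibble(
      n_rules = kk,
      proportion = sum(areas[valid & count == kk]) / denom
    )
  })
  structure(
    list(
      count = count, summary = summary, union_proportion = union_prop,
      lat = ref$lat, lon = ref$lon
    ),
    class = "bioclim_overlap"
  )
}
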