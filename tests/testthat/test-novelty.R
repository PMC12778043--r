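test_that("novelty categories follow the occurrence table", {
  vals <- array(0, c(20, 2, 2))
  vals[11:20, 1, 1] <- 1 # new: modern only
  vals[1:10, 2, 1] <- 1 # past: baseline only
  vals[, 1, 2] <- 1 # both
  cube <- manual_cube("ROS", vals, years = 1951:1970)
  nv <- novelty_mask(cube, event_rule("ROS", ">", 0),
    baseline = c(1951, 1960), modern = c(1961, 1970)
  )
  expect_equal(nv$category[1, 1], "new")
  expect_equal(nv$category[2, 1], "past")
  expect_equal(nv$category[1, 2], "both")
  expect_equal(nv$category[2, 2], "neither")
  areas <- cell_areas(cube$lat, cube$lon)
  expect_equal(
    nv$summary$proportion[nv$summary$category == "new"],
    areas[1, 1] / sum(areas)
  )
  # rule satisfied nowhere: no new, no past
  empty <- novelty_mask(
    manual_cube("ROS", array(0, c(20, 2, 2)), years = 1951:1970),
    event_rule("ROS", ">", 0), c(1951, 1960), c(1961, 1970)
  )
  expect_true(all(
    empty$summary$proportion[empty$summary$category %in% c("new", "past")] == 0
  ))
  expect_error(
    novelty_mask(cube, event_rule("ROS", ">", 0), c(1951, 1965), c(1960, 1970)),
    class = "bioclim_overlapping_periods"
  )
})

test_that("swapping the periods swaps new and past exactly", {
  set.seed(53)
  cube <- manual_cube("ROS", array(rbinom(30 * 16, 1, 0.1), c(30, 4, 4)),
    years = 1951:1980
  )
  rule <- event_rule("ROS", ">", 0)
  fwd <- novelty_mask(cube, rule, c(1951, 1962), c(1969, 1980))
  bwd <- novelty_mask(cube, rule, c(1969, 1980), c(1951, 1962))
  expect_identical(fwd$category == "new", bwd$category == "past")
  expect_identical(fwd$category == "past", bwd$category == "new")
})

test_that("proportions are invariant to rotating the grid in longitude", {
  set.seed(59)
  vals <- array(rbinom(20 * 25, 1, 0.15), c(20, 5, 5))
  cube <- manual_cube("ROS", vals, years = 1951:1970)
  rot <- manual_cube("ROS", vals[, , c(3:5, 1:2)], years = 1951:1970)
  rule <- event_rule("ROS", ">", 0)
  a <- novelty_mask(cube, rule, c(1951, 1960), c(1961, 1970))
  b <- novelty_mask(rot, rule, c(1951, 1960), c(1961, 1970))
  expect_equal(a$summary$proportion, b$summary$proportion)
})

test_that("masked pixels leave the denominator", {
  vals <- array(1, c(20, 2, 2))
  land <- matrix(c(TRUE, TRUE, TRUE, FALSE), 2, 2)
  cube <- manual_cube("ROS", vals, years = 1951:1970, land = land)
  cube$data$ROS[, 2, 2] <- NA
  nv <- novelty_mask(cube, event_rule("ROS", ">", 0),
    c(1951, 1960), c(1961, 1970)
  )
  expect_equal(nv$category[2, 2], "masked")
  expect_equal(
    nv$summary$proportion[nv$summary$category == "both"], 1
  )
})

test_that("overlap counts and the union obey set arithmetic", {
  mk_mask <- function(new_cells) {
    vals <- array(0, c(20, 3, 3))
    for (cell in new_cells) vals[11:20, cell[1], cell[2]] <- 1
    novelty_mask(
      manual_cube("ROS", vals, years = 1951:1970),
      event_rule("ROS", ">", 0), c(1951, 1960), c(1961, 1970)
    )
  }
  m1 <- mk_mask(list(c(1, 1)))
  m2 <- mk_mask(list(c(3, 3)))
  ov1 <- overlap_count(list(m1))
  expect_identical(ov1$count == 1, m1$category == "new")
  # disjoint new areas: union proportion adds
  ov <- overlap_count(list(m1, m2))
  p1 <- m1$summary$proportion[m1$summary$category == "new"]
  p2 <- m2$summary$proportion[m2$summary$category == "new"]
  expect_equal(ov$union_proportion, p1 + p2, tolerance = 1e-12)
  # identical masks: max count = n, union = single-mask proportion
  ov6 <- overlap_count(rep(list(m1), 6))
  expect_equal(max(ov6$count), 6)
  expect_equal(ov6$union_proportion, p1, tolerance = 1e-12)
  # union bounds
  expect_gte(ov$union_proportion, max(p1, p2))
  expect_lte(ov$union_proportion, p1 + p2 + 1e-12)
  bad <- m1
  bad$lat <- bad$lat + 5
  expect_error(
    overlap_count(list(m1, bad)),
    class = "bioclim_grid_mismatch"
  )
})

test_that("injected events are flagged new at exactly the injected pixels", {
  cfg <- scenario_preset("event_injection",
    tiny_config(nlat = 4, nlon = 4, years = c(1950, 1989), seed = 61),
    years = 1975:1980, lat = c(2, 3), lon = 2, n_per_year = 2
  )
  w <- generate_weather(cfg)
  cube <- compute_annual_indicators(
    w, indicator_config(reference_years = c(1950, 1979))
  )
  nv <- novelty_mask(cube, event_rule("ROS", ">", 0),
    baseline = c(1950, 1969), modern = c(1970, 1989)
  )
  expect_identical(which(nv$category == "new"), c(
    which(matrix(seq_len(16), 4, 4) == 6), # (2,2)
    which(matrix(seq_len(16), 4, 4) == 7) # (3,2)
  ))
  expect_equal(sum(nv$category == "past"), 0)
})
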