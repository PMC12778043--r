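# End-to-end pipeline: weather -> indicators -> trends -> clusters ->
# areas -> novelty -> synthesis, with resumable stages and a reproducibility
# manifest.

#' Pipeline configuration
#'
#' Bundles every stage's configuration and the analysis periods. Periods
#' default to the conventions of the study design: the full span, the most
#' recent 30 years, a baseline of the first 30 years, a modern window equal
#' to the recent one, an anomaly baseline of years 2-31 (1951-1980 for a
#' 1950 start), and a 30-year climatology window ending 2 years before the
#' span ends (1991-2020 for a 2022 end).
#'
#' @param weather an [weather_config()] for the synthetic generator, or a
#'   path to a directory readable by [read_weather()].
#' @param indicators an [indicator_config()].
#' @param periods named list overriding any of `full`, `recent`,
#'   `baseline`, `modern`, `anomaly_baseline`, `climatology`.
#' @param trend_variables indicators to map trends for.
#' @param tundra_fraction,ice_fraction biome/ice mask targets.
#' @param k,cluster_seed,n_init KMeans settings.
#' @param smooth anomaly smoothing window (years).
#' @param seed master seed (propagated to the weather config and masks).
#' @return An object of class `bioclim_pipeline_config`.
#' @export
pipeline_config <- function(weather = weather_config(),
                            indicators = indicator_config(),
                            periods = list(),
                            trend_variables = bioclim_indicator_vars(),
                            tundra_fraction = 0.4, ice_fraction = 0,
                            k = 6, cluster_seed = 1L, n_init = 10,
                            smooth = 5, seed = NULL) {
  if (inherits(weather, "bioclim_config")) {
    if (!is.null(seed)) weather$seed <- as.integer(seed)
    span <- weather$years
  } else if (is.character(weather)) {
    meta <- read_meta(weather, "bioclim_weather")
    span <- as.integer(meta$years)
  } else {
    abort("`weather` must be an bioclim_config or a dataset path.")
  }
  y0 <- span[1]
  y1 <- span[2]
  ny <- y1 - y0 + 1L
  half <- min(30L, ny %/% 2L) # shrink the 30-year windows on short spans
  defaults <- list(
    full = c(y0, y1),
    recent = c(max(y0, y1 - 29L), y1),
    baseline = c(y0, y0 + half - 1L),
    modern = c(y1 - half + 1L, y1),
    anomaly_baseline = c(min(y0 + 1L, y1), min(y0 + 30L, y1)),
    climatology = c(max(y0, y1 - 31L), max(y0, y1 - 2L))
  )
  for (nm in names(periods)) defaults[[nm]] <- periods[[nm]]
  for (nm in names(defaults)) check_period(defaults[[nm]], span, nm)
  if (defaults$baseline[2] >= defaults$modern[1]) {
    abort("baseline and modern periods must not overlap.")
  }
  structure(
    list(
      weather = weather, indicators = indicators, periods = defaults,
      trend_variables = trend_variables,
      tundra_fraction = tundra_fraction, ice_fraction = ice_fraction,
      k = k, cluster_seed = as.integer(cluster_seed), n_init = n_init,
      smooth = smooth,
      seed = if (inherits(weather, "bioclim_config")) weather$seed else seed
    ),
    class = "bioclim_pipeline_config"
  )
}

pipeline_stage <- function(name, code) {
  tryCatch(force(code), error = function(e) {
    abort(sprintf("stage `%s` failed: %s", name, conditionMessage(e)),
      class = "bioclim_stage_error"
    )
  })
}

#' Run the full bioclimatic analysis pipeline
#'
#' Executes indicators, trend maps, climate clustering, event-area
#' accounting, novelty mapping and the bivariate synthesis in order,
#' writing each stage's result as plain-text files under `out_dir`. A
#' stage whose output files already exist is skipped unless `force = TRUE`
#' (the indicator cube is read back instead of recomputed). A
#' `manifest.json` records the configuration hash, the seed, and a content
#' hash per output file, so a rerun with an unchanged configuration is
#' verifiably identical.
#'
#' @param config an [pipeline_config()].
#' @param out_dir output directory.
#' @param force recompute stages whose outputs already exist.
#' @return Invisibly, a list with the stage results (`weather`, `cube`,
#'   `trends`, `clusters`, `areas`, `novelty`, `synthesis`) and the
#'   `manifest`.
#' @export
run_pipeline <- function(config, out_dir, force = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pd <- config$periods

  weather <- pipeline_stage("weather", {
    if (is.character(config$weather)) {
      read_weather(config$weather)
    } else {
      generate_weather(config$weather)
    }
  })
  masks <- pipeline_stage("masks", {
    generate_region_masks(
      weather$lat, weather$lon,
      tundra_fraction = config$tundra_fraction,
      ice_fraction = config$ice_fraction,
      seed = config$seed %||% 1L
    )
  })

  cube_dir <- file.path(out_dir, "indicators")
  cube <- pipeline_stage("indicators", {
    if (dir.exists(cube_dir) && !force) {
      read_cube(cube_dir)
    } else {
      cc <- compute_annual_indicators(weather, config$indicators)
      write_cube(cc, cube_dir)
      cc
    }
  })

  write_stage_csv <- function(df, fname) {
    f <- file.path(out_dir, fname)
    if (!file.exists(f) || force) readr::write_csv(df, f, progress = FALSE)
    f
  }

  trends <- pipeline_stage("trends", {
    maps <- purrr::map_dfr(config$trend_variables, function(v) {
      dplyr::mutate(
        as_tibble(trend_map(cube, v, pd$full)),
        variable = v, .before = 1
      )
    })
    pair <- purrr::map_dfr(config$trend_variables, function(v) {
      dplyr::mutate(
        region_trend_pair(
          cube, masks$biome, v,
          periods = list(full = pd$full, recent = pd$recent)
        ),
        variable = v, .before = 1
      )
    })
    list(
      maps = maps, regional = pair,
      files = c(
        write_stage_csv(maps, "trend_maps.csv"),
        write_stage_csv(pair, "trend_regional.csv")
      )
    )
  })

  clusters <- pipeline_stage("clusters", {
    feats <- climatology_features(weather, pd$climatology)
    cl <- fit_clusters(
      normalize_features(feats),
      k = config$k, seed = config$cluster_seed, n_init = config$n_init
    )
    list(
      model = cl, features = feats,
      files = c(
        write_stage_csv(cl$labels, "cluster_labels.csv"),
        write_stage_csv(cluster_summary(cl, feats), "cluster_summary.csv")
      )
    )
  })

  rules <- default_event_rules(cube)
  areas <- pipeline_stage("areas", {
    series <- purrr::imap_dfr(rules, function(rule, nm) {
      dplyr::mutate(
        as_tibble(annual_event_area(cube, rule)),
        variable = nm, .before = 1
      )
    })
    tr <- purrr::imap_dfr(rules, function(rule, nm) {
      s <- annual_event_area(cube, rule)
      dplyr::mutate(
        area_trend(s, periods = list(full = pd$full, recent = pd$recent)),
        variable = nm, .before = 1
      )
    })
    list(
      series = series, trends = tr,
      files = c(
        write_stage_csv(series, "event_areas.csv"),
        write_stage_csv(tr, "event_area_trends.csv")
      )
    )
  })

  novelty <- pipeline_stage("novelty", {
    nm_list <- purrr::map(
      rules, novelty_mask,
      cube = cube, baseline = pd$baseline, modern = pd$modern
    )
    summ <- purrr::imap_dfr(nm_list, function(m, nm) {
      dplyr::mutate(m$summary, variable = nm, .before = 1)
    })
    ov <- overlap_count(nm_list)
    summ <- dplyr::bind_rows(summ, tibble(
      variable = "union", category = "new", area_km2 = NA_real_,
      proportion = ov$union_proportion
    ))
    list(
      masks = nm_list, overlap = ov, summary = summ,
      files = write_stage_csv(summ, "novelty_summary.csv")
    )
  })

  synthesis <- pipeline_stage("synthesis", {
    tests <- purrr::map(
      c(seasonal_variables(), event_variables()),
      function(v) period_change_test(cube, v, pd$baseline, pd$modern)
    )
    sm <- synthesis_map(tests)
    list(
      map = sm,
      files = write_stage_csv(as_tibble(sm), "synthesis_map.csv")
    )
  })

  files <- c(
    list.files(cube_dir, full.names = TRUE),
    trends$files, clusters$files, areas$files, novelty$files,
    synthesis$files
  )
  manifest <- list(
    config_hash = rlang::hash(config),
    seed = config$seed,
    weather_hash = rlang::hash(weather$data),
    outputs = as.list(setNames(
      unname(tools::md5sum(sort(files))),
      basename(sort(files))
    ))
  )
  jsonlite::write_json(
    manifest, file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(list(
    weather = weather, masks = masks, cube = cube, trends = trends,
    clusters = clusters, areas = areas, novelty = novelty,
    synthesis = synthesis, manifest = manifest
  ))
}

#' Read a pipeline configuration from YAML
#'
#' The file may contain top-level `weather:`, `indicators:` and
#' `pipeline:` blocks whose keys mirror the arguments of
#' [weather_config()], [indicator_config()] and [pipeline_config()].
#'
#' @param path YAML file.
#' @return An [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  w <- do.call(weather_config, y$weather %||% list())
  ic <- do.call(indicator_config, y$indicators %||% list())
  args <- y$pipeline %||% list()
  args$weather <- w
  args$indicators <- ic
  do.call(pipeline_config, args)
}
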