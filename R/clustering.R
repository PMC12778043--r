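# Climate classification: per-pixel climatology features, Gaussian
# normalization, KMeans clusters, and feature correlations.

#' Per-pixel climatology features for climate classification
#'
#' Computes, for each land pixel and averaged over a period of years, the
#' three classification features: mean annual 2-m temperature (deg C),
#' annual precipitation sum (mm), and the annual maximum monthly
#' mean temperature difference (deg C). The temperature range is computed
#' within each year (max minus min monthly mean) and then averaged across
#' years; set `range_mode = "climatology"` to instead take the range of the
#' long-term monthly climatology.
#'
#' @param weather an [bioclim_weather()] object.
#' @param period `c(first, last)` averaging years (default 1991-2020 clipped
#'   to the span).
#' @param range_mode `"within_year"` (default) or `"climatology"`.
#' @return A tibble of class `bioclim_features` with columns `lat`, `lon`,
#'   `land`, `temp_mean`, `precip_sum`, `temp_range`; attribute `period`;
#'   attribute `normalized = FALSE`.
#' @export
climatology_features <- function(weather, period = c(1991, 2020),
                                 range_mode = c("within_year", "climatology")) {
  range_mode <- match.arg(range_mode)
  time <- weather$time
  years <- sort(unique(time$year))
  check_period(period, years)
  sel <- time$year >= period[1] & time$year <= period[2]
  yrs <- time$year[sel]
  mons <- time$month[sel]
  nlat <- length(weather$lat)
  nlon <- length(weather$lon)
  grid <- expand.grid(i = seq_len(nlat), j = seq_len(nlon))
  rows <- purrr::pmap_dfr(grid, function(i, j) {
    if (!weather$land[i, j]) {
      return(tibble(
        lat = weather$lat[i], lon = weather$lon[j], land = FALSE,
        temp_mean = NA_real_, precip_sum = NA_real_, temp_range = NA_real_
      ))
    }
    t <- weather$data$tmean[sel, i, j]
    p <- weather$data$precip_total[sel, i, j]
    monthly <- tapply(t, list(yrs, mons), mean) # [year x month]
    rng <- if (range_mode == "within_year") {
      mean(apply(monthly, 1, max) - apply(monthly, 1, min))
    } else {
      clim <- colMeans(monthly)
      max(clim) - min(clim)
    }
    tibble(
      lat = weather$lat[i], lon = weather$lon[j], land = TRUE,
      temp_mean = mean(t),
      precip_sum = sum(p) / length(unique(yrs)),
      temp_range = rng
    )
  })
  structure(rows,
    class = c("bioclim_features", class(rows)),
    period = period, normalized = FALSE, norm_params = NULL
  )
}

feature_cols <- function() c("temp_mean", "precip_sum", "temp_range")

#' Gaussian normalization of climatology features
#'
#' Centres and scales each feature to mean 0 and standard deviation 1 over
#' land pixels, so all three carry similar weight in clustering. The
#' normalization parameters are stored so the transform can be inverted.
#'
#' @param features an `bioclim_features` tibble.
#' @return The normalized `bioclim_features` (attribute `normalized = TRUE`,
#'   `norm_params` holding per-feature mean and sd).
#' @export
normalize_features <- function(features) {
  land <- features$land
  if (sum(land) < 2L) abort("need at least 2 land pixels.")
  params <- purrr::map(feature_cols(), function(col) {
    m <- mean(features[[col]][land])
    s <- sd(features[[col]][land])
    if (!is.finite(s) || s == 0) {
      abort(sprintf("feature `%s` has zero variance.", col),
        class = "bioclim_zero_variance"
      )
    }
    list(mean = m, sd = s)
  })
  names(params) <- feature_cols()
  out <- features
  for (col in feature_cols()) {
    out[[col]] <- (out[[col]] - params[[col]]$mean) / params[[col]]$sd
  }
  attr(out, "normalized") <- TRUE
  attr(out, "norm_params") <- params
  out
}

#' Invert [normalize_features()]
#' @param features a normalized `bioclim_features`.
#' @return Features on the original scale.
#' @export
denormalize_features <- function(features) {
  params <- attr(features, "norm_params")
  if (is.null(params)) abort("features are not normalized.")
  out <- features
  for (col in feature_cols()) {
    out[[col]] <- out[[col]] * params[[col]]$sd + params[[col]]$mean
  }
  attr(out, "normalized") <- FALSE
  attr(out, "norm_params") <- NULL
  out
}

#' KMeans climate clusters from normalized climatology features
#'
#' Standard KMeans on the (normalized) feature triplet over land pixels.
#' Cluster numbering follows the algorithm's arbitrary order, as in the
#' atlas workflow this mirrors; evaluation should therefore use
#' label-permutation-invariant scores.
#'
#' @param features an `bioclim_features` tibble (normalize first; a warning
#'   is raised otherwise).
#' @param k number of clusters (default 6).
#' @param seed RNG seed for the restarts.
#' @param n_init number of random restarts (default 10).
#' @return An object of class `bioclim_clusters`: centroid tibble, per-pixel
#'   label tibble, total within-cluster sum of squares (`inertia`), `k` and
#'   `seed`.
#' @export
fit_clusters <- function(features, k = 6, seed = 1L, n_init = 10) {
  if (!isTRUE(attr(features, "normalized"))) {
    warn("features are not normalized; clustering raw scales.")
  }
  land <- features$land
  x <- as.matrix(features[land, feature_cols()])
  if (k < 1 || k > nrow(x)) abort("`k` must be between 1 and #land pixels.")
  km <- with_stream(seed, "kmeans", {
    kmeans(x, centers = k, nstart = n_init, iter.max = 100)
  })
  labels <- rep(NA_integer_, nrow(features))
  labels[land] <- km$cluster
  structure(
    list(
      centers = as_tibble(km$centers),
      labels = tibble(
        lat = features$lat, lon = features$lon, cluster = labels
      ),
      inertia = km$tot.withinss, k = k, seed = seed,
      norm_params = attr(features, "norm_params")
    ),
    class = "bioclim_clusters"
  )
}

#' @export
print.bioclim_clusters <- function(x, ...) {
  cat(sprintf(
    "<bioclim_clusters> k = %d, inertia = %.3f, %d labelled pixels\n",
    x$k, x$inertia, sum(!is.na(x$labels$cluster))
  ))
  invisible(x)
}

#' @export
tidy.bioclim_clusters <- function(x, ...) {
  dplyr::mutate(x$centers, cluster = dplyr::row_number(), .before = 1)
}

#' @export
glance.bioclim_clusters <- function(x, ...) {
  tibble(k = x$k, inertia = x$inertia, seed = x$seed)
}

#' @export
augment.bioclim_clusters <- function(x, ...) x$labels

#' Cluster labels as a `[lat, lon]` matrix usable as a region map
#' @param clusters an `bioclim_clusters` object.
#' @return Integer matrix of labels (`NA` off-land).
#' @export
cluster_raster <- function(clusters) {
  lat <- sort(unique(clusters$labels$lat))
  lon <- sort(unique(clusters$labels$lon))
  m <- matrix(NA_integer_, length(lat), length(lon))
  m[cbind(
    match(clusters$labels$lat, lat),
    match(clusters$labels$lon, lon)
  )] <- clusters$labels$cluster
  m
}

#' Pearson correlations between the clustering features
#' @param features an `bioclim_features` tibble.
#' @return Symmetric 3x3 correlation matrix with unit diagonal.
#' @export
feature_correlations <- function(features) {
  x <- as.matrix(features[features$land, feature_cols()])
  if (nrow(x) < 3L) abort("need at least 3 land pixels.")
  if (any(apply(x, 2, sd) == 0)) {
    abort("zero-variance feature.", class = "bioclim_zero_variance")
  }
  cor(x)
}

#' Per-cluster means and 98% ranges of the raw features
#'
#' @param clusters an `bioclim_clusters` object.
#' @param features the (raw-scale) `bioclim_features` used for the fit.
#' @return Tibble: cluster, feature, mean, q01, q99, n_pixels.
#' @export
cluster_summary <- function(clusters, features) {
  df <- dplyr::bind_cols(
    features, cluster = clusters$labels$cluster
  )
  df <- dplyr::filter(df, !is.na(.data$cluster))
  tidyr::pivot_longer(df, dplyr::all_of(feature_cols()),
    names_to = "feature"
  ) |>
    dplyr::group_by(.data$cluster, .data$feature) |>
    dplyr::summarise(
      mean = mean(.data$value),
      q01 = quantile(.data$value, 0.01, names = FALSE),
      q99 = quantile(.data$value, 0.99, names = FALSE),
      n_pixels = dplyr::n(), .groups = "drop"
    )
}
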