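# Independent reference implementations ("oracles") kept deliberately naive:
# explicit loops and direct transcriptions of the definitions, sharing no
# code with the package engine.

oracle_sen_slope <- function(v, t = seq_along(v)) {
  slopes <- c()
  n <- length(v)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (t[j] != t[i]) slopes <- c(slopes, (v[j] - v[i]) / (t[j] - t[i]))
    }
  }
  median(slopes)
}

oracle_mk_s <- function(v) {
  s <- 0
  n <- length(v)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) s <- s + sign(v[j] - v[i])
  }
  s
}

# exact two-sided Mann-Kendall p by enumerating value permutations
oracle_mk_exact_p <- function(v) {
  perms <- function(x) {
    if (length(x) <= 1) return(list(x))
    out <- list()
    for (i in seq_along(x)) {
      for (rest in perms(x[-i])) out <- c(out, list(c(x[i], rest)))
    }
    out
  }
  s_obs <- oracle_mk_s(v)
  s_all <- vapply(perms(v), oracle_mk_s, numeric(1))
  mean(abs(s_all) >= abs(s_obs))
}

oracle_longest_run <- function(mask) {
  best <- 0
  cur <- 0
  for (x in mask) {
    cur <- if (isTRUE(x)) cur + 1 else 0
    best <- max(best, cur)
  }
  best
}

# naive per-pixel indicator reference: day loops straight from definitions
oracle_indicators_pixel <- function(tmean, tmax, tskin, liquid, snowd, wind,
                                    dew, time, cfg) {
  years <- sort(unique(time$year))
  es <- function(t) 0.61094 * exp(17.625 * t / (t + 243.04))
  vpd <- es(tmean) - es(dew)
  snow <- snowd >= cfg$snow_depth_threshold
  hwe_thr <- quantile(wind, cfg$hwe_percentile / 100, names = FALSE)

  # magnitude-index reference pieces
  ref_sel <- time$year >= cfg$reference_years[1] &
    time$year <= cfg$reference_years[2]
  ref_piece <- function(x) {
    thr <- numeric(365)
    for (d in 1:365) {
      win <- ((d - cfg$magnitude_half_width):(d + cfg$magnitude_half_width) - 1) %% 365 + 1
      thr[d] <- quantile(x[ref_sel & time$doy %in% win],
        cfg$magnitude_percentile / 100,
        names = FALSE
      )
    }
    amax <- c()
    for (y in unique(time$year[ref_sel])) {
      amax <- c(amax, max(x[ref_sel & time$year == y]))
    }
    list(
      thr = thr, q25 = quantile(amax, 0.25, names = FALSE),
      q75 = quantile(amax, 0.75, names = FALSE)
    )
  }
  mag_index <- function(x, doy, piece) {
    iqr <- piece$q75 - piece$q25
    summer <- noleap_calendar(c(2001, 2001))
    summer <- summer$doy[summer$month %in% cfg$summer_months]
    best <- 0
    run <- c()
    for (d in seq_along(x)) {
      hit <- (doy[d] %in% summer) && x[d] > piece$thr[doy[d]]
      if (hit) {
        run <- c(run, x[d])
      } else {
        if (length(run) >= cfg$min_run) {
          best <- max(best, sum(pmax((run - piece$q25) / iqr, 0)))
        }
        run <- c()
      }
    }
    if (length(run) >= cfg$min_run) {
      best <- max(best, sum(pmax((run - piece$q25) / iqr, 0)))
    }
    best
  }
  hw_piece <- ref_piece(tmax)
  vpd_piece <- ref_piece(vpd)

  out <- list()
  for (k in seq_along(years)) {
    y <- years[k]
    ci <- which(time$year == y)
    # growing season: longest run tmean >= threshold, by scan
    best_len <- 0
    best_start <- NA
    cur_len <- 0
    for (d in seq_along(ci)) {
      if (tmean[ci[d]] >= cfg$gsl_threshold) {
        cur_len <- cur_len + 1
        if (cur_len > best_len) {
          best_len <- cur_len
          best_start <- d - cur_len + 1
        }
      } else {
        cur_len <- 0
      }
    }
    gdd <- 0
    fgs <- 0
    if (best_len > 0) {
      for (d in best_start:(best_start + best_len - 1)) {
        if (tmean[ci[d]] > cfg$gdd_threshold) {
          gdd <- gdd + (tmean[ci[d]] - cfg$gdd_threshold)
        }
        if (tskin[ci[d]] < 0) fgs <- fgs + tskin[ci[d]]
      }
    }
    swi <- 0
    for (m in 1:12) {
      mm <- mean(tmean[ci][time$month[ci] == m])
      if (mm > cfg$swi_threshold) swi <- swi + mm
    }
    hwe <- sum(wind[ci] > hwe_thr)
    hwmi <- mag_index(tmax[ci], time$doy[ci], hw_piece)
    vpdi <- mag_index(vpd[ci], time$doy[ci], vpd_piece)

    hi <- which((time$year == y - 1 & time$month >= cfg$hydro_start_month) |
      (time$year == y & time$month < cfg$hydro_start_month))
    if (length(hi) == 365) {
      fdd <- sum(pmin(tmean[hi], 0))
      ssl <- oracle_longest_run(snow[hi])
      ros <- sum(snow[hi] & liquid[hi] > cfg$ros_threshold)
      wwe <- sum(snow[hi] & time$month[hi] %in% cfg$wwe_months &
        tmean[hi] >= cfg$wwe_threshold)
    } else {
      fdd <- ssl <- ros <- wwe <- NA
    }
    out[[k]] <- c(
      GDD = gdd, GSL = best_len, FGS = fgs, FDD = fdd, SSL = ssl,
      SWI = swi, ROS = ros, WWE = wwe, HWMI = hwmi, VPDI = vpdi, HWE = hwe
    )
  }
  do.call(rbind, out)
}

# adjusted Rand index (contingency-table formula)
oracle_ari <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- comb2(sum(tab))
  exp_idx <- sum_a * sum_b / n
  (sum_ij - exp_idx) / ((sum_a + sum_b) / 2 - exp_idx)
}

# closed-form spherical band area between two latitudes, km^2
oracle_band_area <- function(phi_bot, phi_top, lon_width_deg = 360) {
  r <- 6371
  (lon_width_deg / 360) * 2 * pi * r^2 *
    (sin(phi_top * pi / 180) - sin(phi_bot * pi / 180))
}
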