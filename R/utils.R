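# Internal helpers: the 365-day no-leap calendar, run-length scans, and
# small validation utilities shared across modules.

.MONTH_LENGTHS <- c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)

#' Build the daily time table for a span of years (365-day calendar)
#'
#' The package uses a no-leap calendar: every year has 365 days, so
#' day-of-year climatology windows line up exactly across years.
#'
#' @param years integer vector of length 2, first and last year (inclusive).
#' @return A tibble with columns `year`, `month`, `day`, `doy`.
#' @export
noleap_calendar <- function(years) {
  stopifnot(length(years) == 2L, years[2] >= years[1])
  yr <- seq.int(years[1], years[2])
  month <- rep.int(seq_len(12L), .MONTH_LENGTHS)
  day <- unlist(lapply(.MONTH_LENGTHS, seq_len), use.names = FALSE)
  tibble(
    year = rep(yr, each = 365L),
    month = rep(month, length(yr)),
    day = rep(day, length(yr)),
    doy = rep(seq_len(365L), length(yr))
  )
}

# longest run of TRUE; returns list(start, end, length); length 0 if none
longest_true_run <- function(x) {
  x[is.na(x)] <- FALSE
  r <- rle(x)
  if (!any(r$values)) {
    return(list(start = NA_integer_, end = NA_integer_, length = 0L))
  }
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  idx <- which(r$values)
  best <- idx[which.max(r$lengths[idx])]
  list(start = starts[best], end = ends[best], length = r$lengths[best])
}

check_number <- function(x, name, min = -Inf, max = Inf,
                         strict_min = FALSE, strict_max = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  lo_ok <- if (strict_min) x > min else x >= min
  hi_ok <- if (strict_max) x < max else x <= max
  if (!lo_ok || !hi_ok) {
    abort(sprintf(
      "`%s` = %g is outside its allowed range %s%g, %g%s.", name, x,
      if (strict_min) "(" else "[", min, max, if (strict_max) ")" else "]"
    ))
  }
  invisible(x)
}

check_period <- function(period, years, name = "period") {
  if (length(period) != 2L || period[2] < period[1]) {
    abort(sprintf("`%s` must be c(first_year, last_year).", name))
  }
  if (period[1] < min(years) || period[2] > max(years)) {
    abort(sprintf(
      "`%s` (%d-%d) lies outside the data span (%d-%d).",
      name, period[1], period[2], min(years), max(years)
    ))
  }
  invisible(period)
}

# deterministic per-variable RNG stream: a distinct 31-bit seed derived from
# the master seed and the variable name, so adding a variable to the
# generator never perturbs the streams of the others
stream_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((abs(seed) * 7919 + h * 104729) %% 2147483647)
}

with_stream <- function(seed, name, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(stream_seed(seed, name))
  force(code)
}

# shrinking-window centred moving average (window w, odd recommended)
moving_average <- function(x, w) {
  if (w <= 1L) return(x)
  h <- floor(w / 2)
  n <- length(x)
  vapply(seq_len(n), function(i) {
    j <- max(1L, i - h):min(n, i + h)
    mean(x[j], na.rm = TRUE)
  }, numeric(1))
}
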