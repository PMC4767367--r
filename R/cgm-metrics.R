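#' A clock-time window of the day
#'
#' Half-open window `[start, end)` of clock time, possibly wrapping
#' midnight. `start == end` denotes the full day. Times are given in hours
#' (possibly fractional) or as `"HH:MM"` strings.
#'
#' @param start,end Window bounds as hours of day or `"HH:MM"`.
#' @return Object of class `clock_window` with bounds in minutes of day.
#' @export
#' @examples
#' clock_window(3, 6)        # nocturnal
#' clock_window("06:00", "24:00") # diurnal
clock_window <- function(start, end) {
  to_min <- function(x) {
    if (is.character(x)) {
      parts <- as.numeric(strsplit(x, ":", fixed = TRUE)[[1]])
      x <- parts[1] + parts[2] / 60
    }
    as.numeric(x) * 60
  }
  s <- to_min(start) %% 1440
  e0 <- to_min(end)
  e <- if (e0 == 1440) 1440 else e0 %% 1440
  structure(list(start_min = s, end_min = e,
                 wraps_midnight = e < s,
                 full_day = s == e %% 1440),
            class = "clock_window")
}

in_window <- function(clock_min, window) {
  if (window$full_day) return(rep(TRUE, length(clock_min)))
  if (window$wraps_midnight) {
    clock_min >= window$start_min | clock_min < window$end_min
  } else {
    clock_min >= window$start_min & clock_min < window$end_min
  }
}

#' The glycemia/variability windows used throughout the package
#'
#' Full 24-h day, nocturnal 03:00--06:00 and diurnal 06:00--24:00. The hours
#' 00:00--03:00 belong to neither the nocturnal nor the diurnal window; that
#' gap is deliberate and reproduced as such.
#' @return Named list of [clock_window()] objects.
#' @export
default_windows <- function() {
  list(
    mean_24h = clock_window(0, 24),
    mean_nocturnal = clock_window(3, 6),
    mean_diurnal = clock_window(6, 24)
  )
}

#' Mean glucose over a clock-time window
#'
#' Arithmetic mean of all valid samples whose clock time falls inside the
#' window, pooled across the analysis days. The result is reported missing
#' (NA, with a message) when fewer than `min_coverage` of the window's grid
#' slots carry a valid value.
#'
#' @param series A (trimmed) [cgm_series()].
#' @param window A [clock_window()].
#' @param min_coverage Minimum fraction of window grid slots that must be
#'   valid; default 0.7.
#' @return Mean glucose in mmol/L, or `NA` when coverage is insufficient.
#' @export
window_mean <- function(series, window, min_coverage = 0.7) {
  sel <- in_window(series$clock_min, window)
  vals <- series$glucose[sel]
  if (!length(vals)) return(NA_real_)
  coverage <- mean(!is.na(vals))
  if (coverage < min_coverage) {
    message(sprintf(
      "window mean for %s skipped: coverage %.0f%% below %.0f%% threshold",
      series$participant_id, 100 * coverage, 100 * min_coverage))
    return(NA_real_)
  }
  mean(vals, na.rm = TRUE)
}

#' 24-hour standard deviation of glucose
#'
#' Sample standard deviation (n - 1 denominator) of all valid samples.
#' By default one pooled SD over the whole trimmed record; `per_day = TRUE`
#' instead averages the daily SDs of days with at least two valid samples.
#'
#' @param series A (trimmed) [cgm_series()].
#' @param per_day Average per-day SDs instead of pooling; default `FALSE`.
#' @return SD in mmol/L, or `NA` with fewer than 2 valid samples.
#' @export
sd_24h <- function(series, per_day = FALSE) {
  if (per_day) {
    sds <- tapply(series$glucose, series$day_index, function(v) {
      v <- v[!is.na(v)]
      if (length(v) >= 2) stats::sd(v) else NA_real_
    })
    sds <- sds[!is.na(sds)]
    return(if (length(sds)) mean(sds) else NA_real_)
  }
  v <- series$glucose[!is.na(series$glucose)]
  if (length(v) < 2) return(NA_real_)
  stats::sd(v)
}

#' Continuous overlapping net glycemic action (CONGA)
#'
#' For every observation with a valid partner `lag_hours` earlier on the
#' grid, the difference current minus lagged is formed; CONGA is the sample
#' standard deviation (n - 1) of those differences. Pairs with either member
#' missing are skipped, not interpolated.
#'
#' @param series A (trimmed) [cgm_series()].
#' @param lag_hours Lag in hours; default 4 (CONGA 4).
#' @return CONGA in mmol/L, or `NA` with fewer than 2 valid differences.
#' @export
conga <- function(series, lag_hours = 4) {
  L <- lag_hours * 60 / series$interval
  if (L != round(L)) {
    stop("lag of ", lag_hours, " h is not a whole number of ",
         series$interval, "-minute samples", call. = FALSE)
  }
  L <- as.integer(L)
  n <- length(series$glucose)
  if (n <= L) return(NA_real_)
  d <- series$glucose[(L + 1L):n] - series$glucose[1:(n - L)]
  d <- d[!is.na(d)]
  if (length(d) < 2) return(NA_real_)
  stats::sd(d)
}

#' Mean of daily differences (MODD)
#'
#' Inter-day variability: for each pair of consecutive analysis days and
#' each grid clock slot valid on both days, the absolute difference of the
#' two glucose values is accumulated; MODD is the mean of all accumulated
#' differences, pooled across all consecutive-day pairs.
#'
#' @param series A (trimmed) [cgm_series()].
#' @return MODD in mmol/L, or `NA` when no slot overlaps across any pair of
#'   consecutive days.
#' @export
modd <- function(series) {
  days <- sort(unique(series$day_index))
  diffs <- numeric(0)
  for (k in seq_len(length(days) - 1)) {
    if (days[k + 1] != days[k] + 1) next # only truly consecutive days
    a <- series$day_index == days[k]
    b <- series$day_index == days[k + 1]
    va <- series$glucose[a][match(series$clock_min[b], series$clock_min[a])]
    vb <- series$glucose[b]
    d <- abs(vb - va)
    diffs <- c(diffs, d[!is.na(d)])
  }
  if (!length(diffs)) return(NA_real_)
  mean(diffs)
}

#' Glucose range
#'
#' Difference between the maximum and minimum valid glucose value of the
#' trimmed record (pooled; `per_day = TRUE` averages daily ranges).
#'
#' @param series A (trimmed) [cgm_series()].
#' @param per_day Average per-day ranges instead of pooling; default `FALSE`.
#' @return Range in mmol/L, or `NA` with no valid samples.
#' @export
glucose_range <- function(series, per_day = FALSE) {
  if (per_day) {
    rs <- tapply(series$glucose, series$day_index, function(v) {
      v <- v[!is.na(v)]
      if (length(v)) diff(range(v)) else NA_real_
    })
    rs <- rs[!is.na(rs)]
    return(if (length(rs)) mean(rs) else NA_real_)
  }
  v <- series$glucose[!is.na(series$glucose)]
  if (!length(v)) return(NA_real_)
  diff(range(v))
}

#' Per-participant glycemia and glycemic-variability summary
#'
#' Computes the seven summary statistics of a trimmed CGM record: three
#' glycemia measures (24-h, nocturnal 03:00--06:00 and diurnal 06:00--24:00
#' window means) and four variability measures (24-h SD, CONGA 4, MODD,
#' range), plus bookkeeping columns. Individual statistics whose
#' preconditions fail are reported `NA` rather than aborting.
#'
#' @param series A trimmed [cgm_series()] (see [trim_to_analysis_days()]).
#' @param windows Named list of the three [clock_window()]s; defaults to
#'   [default_windows()].
#' @param min_coverage Coverage threshold passed to [window_mean()].
#' @param conga_lag_hours CONGA lag, hours (default 4).
#' @return One-row tibble: `participant_id`, `mean_24h`, `mean_nocturnal`,
#'   `mean_diurnal`, `sd_24h`, `conga4`, `modd`, `range`, `n_valid_samples`,
#'   `fraction_missing`.
#' @export
cgm_summary <- function(series, windows = default_windows(),
                        min_coverage = 0.7, conga_lag_hours = 4) {
  tibble::tibble(
    participant_id = series$participant_id,
    mean_24h = window_mean(series, windows$mean_24h, min_coverage),
    mean_nocturnal = window_mean(series, windows$mean_nocturnal, min_coverage),
    mean_diurnal = window_mean(series, windows$mean_diurnal, min_coverage),
    sd_24h = sd_24h(series),
    conga4 = conga(series, conga_lag_hours),
    modd = modd(series),
    range = glucose_range(series),
    n_valid_samples = sum(!is.na(series$glucose)),
    fraction_missing = mean(is.na(series$glucose))
  )
}

#' Summarize a whole cohort of CGM series
#'
#' Applies [trim_to_analysis_days()] and [cgm_summary()] to each series and
#' binds the rows. Series failing to trim (too short) are dropped with a
#' warning naming the participant.
#'
#' @param series_list Named list of [cgm_series()].
#' @inheritParams cgm_summary
#' @return Tibble with one row per summarizable participant.
#' @export
summarize_cohort <- function(series_list, windows = default_windows(),
                             min_coverage = 0.7, conga_lag_hours = 4) {
  rows <- lapply(series_list, function(s) {
    tryCatch(
      cgm_summary(trim_to_analysis_days(s), windows, min_coverage,
                  conga_lag_hours),
      error = function(e) {
        warning("participant ", s$participant_id, " dropped: ",
                conditionMessage(e), call. = FALSE)
        NULL
      })
  })
  dplyr::bind_rows(rows)
}
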