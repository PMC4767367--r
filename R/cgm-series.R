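#' A continuous glucose monitoring series on a fixed sampling grid
#'
#' Container for one participant's interstitial glucose trace: a start
#' timestamp, a nominal sampling interval (minutes) and a vector of glucose
#' values in mmol/L aligned to the grid, with `NA` marking missing samples.
#' Present values must lie in the physiologic range (0, 40) mmol/L.
#'
#' @param participant_id Participant identifier.
#' @param start POSIXct timestamp of the first grid slot.
#' @param interval Sampling interval in minutes (> 0).
#' @param glucose Numeric vector of glucose values (mmol/L), `NA` = missing.
#' @return An object of class `cgm_series` with precomputed clock minutes
#'   (`clock_min`) and calendar day index (`day_index`, 1-based from the
#'   first sample's date) per slot.
#' @export
cgm_series <- function(participant_id, start, interval, glucose) {
  stopifnot(length(interval) == 1, interval > 0, inherits(start, "POSIXct"))
  glucose <- as.numeric(glucose)
  bad <- which(!is.na(glucose) & (glucose <= 0 | glucose >= 40))
  if (length(bad)) {
    stop("glucose values outside (0, 40) mmol/L at positions ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  n <- length(glucose)
  offset_min <- (seq_len(n) - 1) * interval
  start_min_of_day <- as.integer(format(start, "%H", tz = "UTC")) * 60L +
    as.integer(format(start, "%M", tz = "UTC"))
  abs_min <- start_min_of_day + offset_min
  structure(
    list(
      participant_id = participant_id,
      start = start,
      interval = as.integer(interval),
      glucose = glucose,
      clock_min = as.integer(abs_min %% 1440L),
      day_index = as.integer(abs_min %/% 1440L) + 1L
    ),
    class = "cgm_series"
  )
}

#' @export
print.cgm_series <- function(x, ...) {
  cat(sprintf(
    "<cgm_series %s: %d samples @ %d min from %s, %.1f%% missing>\n",
    x$participant_id, length(x$glucose), x$interval,
    format(x$start, "%Y-%m-%d %H:%M", tz = "UTC"),
    100 * mean(is.na(x$glucose))))
  invisible(x)
}

#' Grid timestamps of a CGM series
#' @param series A [cgm_series()].
#' @return POSIXct vector, one per grid slot.
#' @export
series_times <- function(series) {
  series$start + (seq_along(series$glucose) - 1) * series$interval * 60
}

#' Read long-format CGM data into per-participant series
#'
#' Expects columns `participant_id`, `timestamp` (ISO-8601) and a glucose
#' column (`glucose` or `glucose_mmol_l`). Each participant's samples are
#' snapped to a grid of `expected_interval` minutes anchored at their first
#' timestamp (tolerance: half an interval). When two rows land in the same
#' grid slot the first is kept with a warning; unobserved slots between the
#' first and last sample become explicit missing values. Rows with glucose
#' outside (0, 40) mmol/L are dropped with a warning; a malformed timestamp
#' is a hard error naming the offending row.
#'
#' @param path CSV file path.
#' @param expected_interval Nominal sampling interval, minutes.
#' @return Named list of [cgm_series()].
#' @export
read_cgm_csv <- function(path, expected_interval = 5) {
  raw <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  gcol <- intersect(c("glucose", "glucose_mmol_l"), names(raw))[1]
  if (is.na(gcol) || !all(c("participant_id", "timestamp") %in% names(raw))) {
    stop("CGM CSV needs columns participant_id, timestamp, glucose[_mmol_l]",
         call. = FALSE)
  }
  ts <- as.POSIXct(rep(NA_real_, nrow(raw)), origin = "1970-01-01",
                   tz = "UTC")
  for (fmt in c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S",
                "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M")) {
    todo <- is.na(ts)
    if (!any(todo)) break
    ts[todo] <- as.POSIXct(strptime(raw$timestamp[todo], fmt, tz = "UTC"))
  }
  if (anyNA(ts)) {
    stop("malformed timestamp at row(s) ",
         paste(utils::head(which(is.na(ts)), 5), collapse = ", "),
         call. = FALSE)
  }
  glucose <- suppressWarnings(as.numeric(raw[[gcol]]))
  if (anyNA(glucose)) {
    stop("non-numeric glucose at row(s) ",
         paste(utils::head(which(is.na(glucose)), 5), collapse = ", "),
         call. = FALSE)
  }
  out_of_range <- glucose <= 0 | glucose >= 40
  if (any(out_of_range)) {
    warning(sum(out_of_range),
            " row(s) with glucose outside (0, 40) mmol/L dropped",
            call. = FALSE)
  }
  keep <- !out_of_range
  df <- tibble::tibble(participant_id = raw$participant_id[keep],
                       ts = ts[keep], glucose = glucose[keep])
  df <- df[order(df$participant_id, df$ts), ]

  split(df, df$participant_id) |>
    lapply(function(d) {
      t0 <- d$ts[1]
      slot <- as.integer(round(as.numeric(difftime(d$ts, t0, units = "mins")) /
                                 expected_interval))
      dup <- duplicated(slot)
      if (any(dup)) {
        warning(sum(dup), " duplicate grid slot(s) for participant ",
                d$participant_id[1], "; first kept", call. = FALSE)
      }
      slot <- slot[!dup]
      vals <- d$glucose[!dup]
      glucose <- rep(NA_real_, max(slot) + 1L)
      glucose[slot + 1L] <- vals
      cgm_series(d$participant_id[1], t0, expected_interval, glucose)
    })
}

#' Drop the first and last monitoring day
#'
#' Sensor readings on the insertion and removal days are the least accurate,
#' so the analysis keeps only full intermediate days: all samples whose
#' calendar date is neither the first nor the last recorded date. For a
#' standard 5-day recording this retains days 2--4, a 72-hour window.
#'
#' @param series A [cgm_series()] spanning at least 3 calendar days.
#' @return A trimmed [cgm_series()] carrying a `trimmed` flag, so applying
#'   the function twice equals applying it once. A warning is issued when
#'   only a single day remains; fewer than one full day is an error.
#' @export
trim_to_analysis_days <- function(series) {
  if (isTRUE(series$trimmed)) return(series) # idempotent on retained span
  days <- unique(series$day_index)
  if (length(days) < 3) {
    stop("insufficient monitoring data: need >= 3 calendar days, got ",
         length(days), call. = FALSE)
  }
  keep_days <- setdiff(days, range(days))
  keep <- series$day_index %in% keep_days
  if (length(keep_days) < 1 || !any(keep)) {
    stop("insufficient monitoring data: no full day remains after trimming",
         call. = FALSE)
  }
  if (length(keep_days) == 1) {
    warning("only one analysis day remains after trimming first/last day",
            call. = FALSE)
  }
  idx <- range(which(keep))
  out <- cgm_series(series$participant_id,
                    series_times(series)[idx[1]],
                    series$interval,
                    series$glucose[idx[1]:idx[2]])
  out$trimmed <- TRUE
  out
}
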