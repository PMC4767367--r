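# Shared fixtures and independent brute-force reference implementations.

MIDNIGHT <- as.POSIXct("2015-03-02 00:00:00", tz = "UTC")

# series from explicit values on a regular grid
make_series <- function(values, interval = 5, start = MIDNIGHT,
                        id = "P0001") {
  cgm_series(id, start, interval, values)
}

# n full days of a repeating daily pattern (one value per grid slot)
make_daily_series <- function(day_values, n_days, interval = 5,
                              start = MIDNIGHT, id = "P0001") {
  stopifnot(length(day_values) == 1440 / interval)
  make_series(rep(day_values, n_days), interval, start, id)
}

# random series with missingness, physiologic range
random_series <- function(n, interval = 5, missing = 0.15,
                          start = MIDNIGHT) {
  v <- pmin(pmax(rnorm(n, 6, 1.2), 2.5), 15)
  v[runif(n) < missing] <- NA
  make_series(v, interval, start)
}

# ---- brute-force oracles (deliberately naive, O(n^2) where natural) ----

naive_window_mean <- function(series, start_hr, end_hr) {
  times <- series_times(series)
  hrs <- as.numeric(format(times, "%H", tz = "UTC")) +
    as.numeric(format(times, "%M", tz = "UTC")) / 60
  sel <- hrs >= start_hr & hrs < end_hr
  mean(series$glucose[sel], na.rm = TRUE)
}

naive_sd <- function(values) {
  v <- values[!is.na(values)]
  m <- sum(v) / length(v)
  sqrt(sum((v - m)^2) / (length(v) - 1))
}

naive_conga <- function(series, lag_hours = 4) {
  times <- series_times(series)
  diffs <- c()
  for (i in seq_along(times)) {
    target <- times[i] - lag_hours * 3600
    j <- which(times == target)
    if (length(j) == 1 && !is.na(series$glucose[i]) &&
        !is.na(series$glucose[j])) {
      diffs <- c(diffs, series$glucose[i] - series$glucose[j])
    }
  }
  if (length(diffs) < 2) return(NA_real_)
  naive_sd(diffs)
}

naive_modd <- function(series) {
  # brute force: for every sample, scan for the sample exactly one calendar
  # day later at the same wall-clock time
  times <- series_times(series)
  key <- paste(as.Date(times, tz = "UTC"), format(times, "%H:%M:%S",
                                                  tz = "UTC"))
  diffs <- c()
  for (i in seq_along(times)) {
    target <- paste(as.Date(times[i], tz = "UTC") + 1,
                    format(times[i], "%H:%M:%S", tz = "UTC"))
    j <- which(key == target)
    if (length(j) == 1 && !is.na(series$glucose[i]) &&
        !is.na(series$glucose[j])) {
      diffs <- c(diffs, abs(series$glucose[j] - series$glucose[i]))
    }
  }
  if (!length(diffs)) return(NA_real_)
  mean(diffs)
}

# fast independent references built on explicit timestamp joins (used where
# many long series are checked)
join_conga <- function(series, lag_hours = 4) {
  t_num <- as.numeric(series_times(series))
  j <- match(t_num - lag_hours * 3600, t_num)
  d <- series$glucose - series$glucose[j]
  d <- d[!is.na(d)]
  if (length(d) < 2) return(NA_real_)
  naive_sd(d)
}

join_modd <- function(series) {
  t_num <- as.numeric(series_times(series))
  j <- match(t_num - 86400, t_num)
  d <- abs(series$glucose - series$glucose[j])
  d <- d[!is.na(d)]
  if (!length(d)) return(NA_real_)
  mean(d)
}

naive_range <- function(values) {
  v <- sort(values[!is.na(values)])
  v[length(v)] - v[1]
}

# hand-rolled one-way cluster sandwich with the HC1-style small-sample factor
naive_cluster_se <- function(X, y, cluster, term) {
  fit <- lm.fit(X, y)
  beta <- fit$coefficients
  u <- y - X %*% beta
  bread <- solve(crossprod(X))
  meat <- matrix(0, ncol(X), ncol(X))
  for (g in unique(cluster)) {
    idx <- which(cluster == g)
    s <- t(X[idx, , drop = FALSE]) %*% u[idx]
    meat <- meat + s %*% t(s)
  }
  G <- length(unique(cluster))
  N <- nrow(X)
  k <- ncol(X)
  c_adj <- (G / (G - 1)) * ((N - 1) / (N - k))
  V <- c_adj * bread %*% meat %*% bread
  sqrt(V[term, term])
}

# small analysis-ready table with singleton clusters
toy_table <- function(a = c(1, 2, 3), b = c(2, 3, 4)) {
  tibble::tibble(
    outcome = c(a, b),
    risk_group = rep(c(FALSE, TRUE), c(length(a), length(b))),
    family_id = sprintf("F%02d", seq_along(c(a, b)))
  )
}

# fast nocturnal-outcome table from a simulated cohort
simulate_outcome_table <- function(cfg, seed) {
  ppl <- simulate_cohort(cfg, seed = seed)
  ser <- simulate_cgm_cohort(ppl, cfg, seed = seed + 1000000L)
  nw <- default_windows()$mean_nocturnal
  ppl$mean_nocturnal <- vapply(
    ser, function(s) window_mean(trim_to_analysis_days(s), nw), numeric(1))
  ppl
}
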