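# Fixed-platform time-series reduction: daylight-window hourly averaging and
# hour-aligned pairing of FUI with water level.

#' Hourly averages inside a daylight window
#'
#' Ocean-colour measurements at a fixed platform are only valid in daylight;
#' samples are restricted to clock hours in `[window_start, window_end]` UTC
#' (defaults 08:00-16:00, inclusive of the 16:00 bin) and averaged per hour.
#' Bins are half-open `[HH:00, HH+1:00)` and labelled by their start instant.
#' Hours of the window with no data are emitted with `NA` values; hours with
#' fewer than half the expected number of samples are flagged
#' `low_coverage` but still reported. Averages use the continuous FUI; any
#' rounding to display classes should happen afterwards.
#'
#' @param ts A data frame with POSIXct `timestamp` and numeric `fui`,
#'   optionally `water_level_m` (e.g. from [generate_tidal_series()]).
#' @param window_start,window_end Whole UTC hours, `window_start <
#'   window_end`.
#' @return A data frame of class `fu_timeseries` with `timestamp` (bin
#'   start), `fui`, `water_level_m` (if present), `n_samples`,
#'   `low_coverage`.
#' @export
hourly_average <- function(ts, window_start = 8, window_end = 16) {
  if (!is.data.frame(ts) || nrow(ts) == 0 ||
      !all(c("timestamp", "fui") %in% names(ts)))
    fu_stop("time series must be a non-empty data frame with timestamp and fui",
            "forelule_empty_series")
  if (window_start >= window_end ||
      window_start != floor(window_start) || window_end != floor(window_end))
    fu_stop("window bounds must be whole hours with start < end", "forelule_domain")
  tt <- as.POSIXct(ts$timestamp, tz = "UTC")
  hod <- as.integer(format(tt, "%H", tz = "UTC"))
  keep <- hod >= window_start & hod <= window_end
  if (!any(keep))
    fu_stop("no samples inside the daylight window", "forelule_empty_series")
  sub <- ts[keep, , drop = FALSE]
  sub_t <- tt[keep]
  bin <- as.POSIXct(trunc(sub_t, units = "hours"), tz = "UTC")
  # full hourly grid over the window for every day touched by the data
  day_rng <- range(as.Date(sub_t))
  days <- seq(day_rng[1], day_rng[2], by = "day")
  grid_bins <- as.POSIXct(outer(as.POSIXct(days, tz = "UTC"),
                                3600 * (window_start:window_end), `+`),
                          tz = "UTC", origin = "1970-01-01")
  grid_bins <- sort(unique(as.numeric(grid_bins)))
  binned <- split(seq_len(nrow(sub)), as.numeric(bin))
  expected <- expected_per_hour(tt)
  has_level <- "water_level_m" %in% names(sub)
  out <- data.frame(timestamp = as.POSIXct(grid_bins, tz = "UTC",
                                           origin = "1970-01-01"))
  out$fui <- NA_real_
  if (has_level) out$water_level_m <- NA_real_
  out$n_samples <- 0L
  for (key in names(binned)) {
    i <- match(as.numeric(key), grid_bins)
    rows <- binned[[key]]
    out$fui[i] <- mean(sub$fui[rows], na.rm = TRUE)
    if (has_level) out$water_level_m[i] <- mean(sub$water_level_m[rows], na.rm = TRUE)
    out$n_samples[i] <- length(rows)
  }
  out$fui[is.nan(out$fui)] <- NA_real_
  out$low_coverage <- out$n_samples < 0.5 * expected
  structure(out, class = c("fu_timeseries", "data.frame"))
}

# expected samples per hour, from the typical sampling interval
expected_per_hour <- function(tt) {
  if (length(tt) < 2) return(1)
  dt <- stats::median(as.numeric(diff(sort(tt)), units = "secs"))
  if (!is.finite(dt) || dt <= 0) return(1)
  max(3600 / dt, 1)
}

#' Pair hourly FUI with water level
#'
#' Aligns FUI and water level on shared hours and quantifies their monotonic
#' association by Spearman rank correlation (see [spearman_assoc()]). Used to
#' ask whether tidal state drives the colour of the water at a platform.
#'
#' @param ts An hourly [fu_timeseries] with both `fui` and `water_level_m`.
#' @return A list of class `fu_level_pairing`: `pairs` (data frame of
#'   complete hour/fui/level rows) and `correlation` (`fu_correlation`).
#' @export
pair_with_water_level <- function(ts) {
  if (!is.data.frame(ts) || !all(c("timestamp", "fui", "water_level_m") %in% names(ts)))
    fu_stop("need a time series with fui and water_level_m columns",
            "forelule_bad_columns")
  ok <- stats::complete.cases(ts$fui, ts$water_level_m)
  pairs <- data.frame(timestamp = ts$timestamp[ok],
                      fui = ts$fui[ok],
                      water_level_m = ts$water_level_m[ok])
  if (nrow(pairs) < 3)
    fu_stop("fewer than 3 complete FUI/water-level pairs",
            "forelule_insufficient_data")
  structure(list(pairs = pairs,
                 correlation = spearman_assoc(pairs$water_level_m, pairs$fui)),
            class = "fu_level_pairing")
}

#' @export
print.fu_level_pairing <- function(x, ...) {
  cat(sprintf("%d hourly FUI/water-level pairs; ", nrow(x$pairs)))
  print(x$correlation)
  invisible(x)
}
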