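#' Daily detection counts
#'
#' A "detection" is a 3-min recording containing any dolphin signal, i.e. a
#' segment whose activity index is positive. Returns, per site and date,
#' the number of detections and the number of recordings monitored.
#'
#' @param records segment-level activity records (`site_id`, `start`,
#'   `index`)
#' @return data.frame with `site_id`, `date`, `n_detections`,
#'   `n_recordings_monitored`
#' @export
daily_detections <- function(records) {
  date <- as.Date(records$start, tz = "UTC")
  key <- paste(records$site_id, date)
  det <- tapply(records$index > 0, key, sum)
  mon <- tapply(records$index, key, length)
  parts <- strsplit(names(det), " ", fixed = TRUE)
  out <- data.frame(site_id = vapply(parts, `[`, "", 1),
                    date = as.Date(vapply(parts, `[`, "", 2)),
                    n_detections = as.integer(det),
                    n_recordings_monitored = as.integer(mon))
  out[order(out$site_id, out$date), ]
}

#' Monthly detection summary
#'
#' Mean and sample standard deviation of daily detections per calendar
#' month, pooled across years. A month observed on a single day has an
#' undefined sd, emitted as `NA`.
#'
#' @param dailies output of [daily_detections()]
#' @return data.frame with `month` (1-12), `mean`, `sd`, `n_days`
#' @export
monthly_summary <- function(dailies) {
  month <- as.POSIXlt(dailies$date)$mon + 1L
  mean_d <- tapply(dailies$n_detections, month, mean)
  sd_d <- tapply(dailies$n_detections, month, function(x)
    if (length(x) > 1) stats::sd(x) else NA_real_)
  n <- tapply(dailies$n_detections, month, length)
  data.frame(month = as.integer(names(mean_d)), mean = as.numeric(mean_d),
             sd = as.numeric(sd_d), n_days = as.integer(n))
}

#' Percentage of monitored days with any detection
#'
#' @param dailies output of [daily_detections()]
#' @return percentage in `[0, 100]`
#' @export
percent_days_present <- function(dailies) {
  if (nrow(dailies) == 0) stop("no monitored days")
  100 * sum(dailies$n_detections > 0) / nrow(dailies)
}

#' Convert a number of fixed-length recordings to hours
#'
#' Bookkeeping helper: `n` recordings of `duration_s` seconds each,
#' expressed in hours and rounded to the nearest hour.
#'
#' @param n_recordings recording count
#' @param duration_s per-recording duration (default 180 s)
#' @return hours (rounded)
#' @export
recording_hours <- function(n_recordings, duration_s = 180) {
  round(n_recordings * duration_s / 3600)
}
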