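#' Ordinal acoustic-activity index for one recording
#'
#' Maps per-recording whistle and burst-pulse counts and the echolocation
#' click rate to the 9-level ordinal index {0, 1, 1.5, 2, 2.5, 3, 3.5, 4}
#' used to quantify dolphin acoustic activity in each 3-min recording.
#' Higher values correspond to greater signal abundance and variety:
#' whistle abundance bands (1-20, 21-40, >= 41), burst-pulse bands
#' (< 10 vs >= 10), and click-rate bands (< 2 vs >= 2 clicks/s).
#'
#' Boundary conventions (the published band edges leave 41 whistles and
#' exactly 10 burst pulses unassigned): whistle bands are closed above as
#' 1-20 / 21-40 / >= 41 and burst-pulse bands as < 10 / >= 10, making the
#' map a total function.
#'
#' @param whistles whistle count (>= 0)
#' @param burst_pulses burst-pulse count (>= 0)
#' @param click_rate echolocation click rate, clicks/s (0 when absent)
#' @return index value; vectorized over the inputs
#' @export
score_recording <- function(whistles, burst_pulses, click_rate) {
  if (any(whistles < 0) || any(burst_pulses < 0) || any(click_rate < 0))
    stop("counts and rates must be >= 0")
  w_band <- findInterval(whistles, c(1, 21, 41))           # 0..3
  echo <- click_rate > 0
  bp <- burst_pulses > 0
  n_other <- echo + bp

  idx <- numeric(length(w_band))
  # --- no whistles ---
  none <- w_band == 0
  idx[none & !echo & !bp] <- 0
  idx[none & !echo & bp] <- ifelse(burst_pulses[none & !echo & bp] < 10, 1, 1.5)
  idx[none & echo & !bp] <- ifelse(click_rate[none & echo & !bp] < 2, 1, 1.5)
  idx[none & echo & bp] <- ifelse(burst_pulses[none & echo & bp] < 10, 1.5, 2.5)
  # --- whistles present: band x number of other signal types ---
  tab <- rbind(c(1, 2, 3),        # 1-20 whistles
               c(1.5, 3, 3.5),    # 21-40
               c(2.5, 3.5, 4))    # >= 41
  some <- w_band > 0
  idx[some] <- tab[cbind(w_band[some], n_other[some] + 1L)]
  idx
}

#' Score a counts table
#'
#' Applies [score_recording()] to each row of a simulated or annotated
#' counts table, yielding per-segment activity records.
#'
#' @param counts data.frame with `whistles`, `burst_pulses`,
#'   `click_rate_hz` (and `start`, `site_id` carried through)
#' @return the input with an `index` column appended
#' @export
score_counts <- function(counts) {
  counts$index <- score_recording(counts$whistles, counts$burst_pulses,
                                  counts$click_rate_hz)
  counts
}

#' Hourly mean acoustic activity (MAA)
#'
#' Averages the per-recording index over the segments whose start time
#' falls inside each clock hour. `maa` is the hourly mean divided by 4 so
#' that it lies in `[0, 1]` (the response variable of the activity model).
#' Hours present in `hour_grid` but containing no segments are emitted with
#' `NA`, never as zero, because an index of 0 is a valid observation.
#'
#' @param records data.frame with POSIXct `start` and `index`
#' @param hour_grid optional POSIXct vector of hour starts to emit
#'   (defaults to the hours that contain data)
#' @return data.frame with `hour_start`, `maa_raw`, `maa`, `n_segments`
#' @export
hourly_mean_activity <- function(records, hour_grid = NULL) {
  key <- floor(as.numeric(records$start) / 3600)
  agg_mean <- tapply(records$index, key, mean)
  agg_n <- tapply(records$index, key, length)
  hours <- as.numeric(names(agg_mean))
  out <- data.frame(hour_start = as.POSIXct(hours * 3600, origin = "1970-01-01",
                                            tz = "UTC"),
                    maa_raw = as.numeric(agg_mean),
                    n_segments = as.integer(agg_n))
  if (!is.null(hour_grid)) {
    grid_key <- floor(as.numeric(hour_grid) / 3600)
    m <- match(grid_key, hours)
    out <- data.frame(hour_start = as.POSIXct(grid_key * 3600,
                                              origin = "1970-01-01", tz = "UTC"),
                      maa_raw = out$maa_raw[m],
                      n_segments = ifelse(is.na(m), 0L, out$n_segments[m]))
  }
  out$maa <- out$maa_raw / 4
  out[order(out$hour_start), c("hour_start", "maa_raw", "maa", "n_segments")]
}

#' Day/night block means of hourly activity
#'
#' Collapses hourly mean activity into one daytime mean (06:00-17:59) and
#' one night-time mean (18:00-05:59) per date. The night block spans
#' midnight and is attributed to the date on which it starts, keeping each
#' night contiguous.
#'
#' @param hourly output of [hourly_mean_activity()]
#' @param day_hours clock hours counted as daytime
#' @return data.frame with `date`, `block` ("day"/"night"), `mean_activity`
#'   (mean of `maa_raw`), `n_hours`
#' @export
day_block_means <- function(hourly, day_hours = 6:17) {
  h <- as.POSIXlt(hourly$hour_start, tz = "UTC")$hour
  date <- as.Date(hourly$hour_start, tz = "UTC")
  block <- ifelse(h %in% day_hours, "day", "night")
  date[block == "night" & h < 12] <- date[block == "night" & h < 12] - 1
  ok <- !is.na(hourly$maa_raw)
  key <- paste(date, block)
  mean_act <- tapply(hourly$maa_raw[ok], key[ok], mean)
  n_hours <- tapply(hourly$maa_raw[ok], key[ok], length)
  parts <- strsplit(names(mean_act), " ", fixed = TRUE)
  out <- data.frame(date = as.Date(vapply(parts, `[`, "", 1)),
                    block = vapply(parts, `[`, "", 2),
                    mean_activity = as.numeric(mean_act),
                    n_hours = as.integer(n_hours))
  out[order(out$date, out$block), ]
}
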