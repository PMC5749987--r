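#' Day/night partition scheme
#'
#' The standard scheme uses daytime 06:00-17:59 and night 18:00-05:59. The
#' distant-site ("array") analysis restricts the day-of daytime block to
#' 10:00-17:59 because more than 90% of recorded detonations fell in that
#' window; its matched day-before block uses the same hours.
#'
#' @param variant "standard" or "array_day_of"
#' @return object of class `day_night_scheme`
#' @export
day_night_scheme <- function(variant = c("standard", "array_day_of")) {
  variant <- match.arg(variant)
  structure(list(variant = variant, day_hours = 6:17,
                 day_of_day_hours = if (variant == "array_day_of") 10:17 else 6:17,
                 night_hours = c(18:23, 0:5)),
            class = "day_night_scheme")
}

#' Label the calendar days around a training event
#'
#' The day of the event is the day of its first detonation (interior days
#' of a multi-day event also carry `day_of`); the day after and the second
#' day after are the two days following the final detonation; the day
#' before is the day preceding the first detonation.
#'
#' @param event one-row data.frame (or list) with `first_undet_day`,
#'   `last_undet_day`
#' @return data.frame with `date` and `label` (factor: day_before, day_of,
#'   day_after, second_day_after)
#' @export
label_event_days <- function(event) {
  d0 <- as.Date(event$first_undet_day)
  d1 <- as.Date(event$last_undet_day)
  stopifnot(d0 <= d1)
  dates <- c(d0 - 1, seq(d0, d1, by = "day"), d1 + 1, d1 + 2)
  labels <- c("day_before", rep("day_of", as.numeric(d1 - d0) + 1),
              "day_after", "second_day_after")
  data.frame(date = dates,
             label = factor(labels, levels = c("day_before", "day_of",
                                               "day_after",
                                               "second_day_after")))
}

#' Baseline eligibility of a training event
#'
#' An event enters the day-scale analysis only if it has a clean 3-day
#' baseline: no detonation (from any event) during the 3 calendar days
#' before its first detonation day, and, when the set of recorded dates is
#' supplied, recordings present on the day before.
#'
#' @param event one-row event (with `event_id`, `first_undet_day`)
#' @param all_events data.frame of every event (including `event`)
#' @param recording_dates optional vector of Dates with data
#' @return logical
#' @export
check_baseline_eligibility <- function(event, all_events,
                                       recording_dates = NULL) {
  d0 <- as.Date(event$first_undet_day)
  window <- seq(d0 - 3, d0 - 1, by = "day")
  others <- all_events[all_events$event_id != event$event_id, , drop = FALSE]
  if (nrow(others)) {
    undet_days <- unlist(lapply(seq_len(nrow(others)), function(i)
      seq(as.Date(others$first_undet_day[i]),
          as.Date(others$last_undet_day[i]), by = "day")))
    if (any(as.Date(undet_days, origin = "1970-01-01") %in% window))
      return(FALSE)
  }
  if (!is.null(recording_dates) && !((d0 - 1) %in% as.Date(recording_dates)))
    return(FALSE)
  TRUE
}

#' Hour-scale comparison windows around a detonation
#'
#' Sums the per-segment activity indices over whole clock hours: the clock
#' hour preceding the detonation's hour, and the first, second and third
#' clock hours after it (the detonation's own hour is not used). A clock
#' hour with no segments yields `NA`, not zero.
#'
#' @param undet_time POSIXct detonation time
#' @param records segment-level activity records (with `start`, `index`)
#' @return named numeric vector `c(sum_before, sum_after_1, sum_after_2,
#'   sum_after_3)`
#' @export
hour_scale_windows <- function(undet_time, records) {
  h0 <- floor(as.numeric(undet_time) / 3600)
  key <- floor(as.numeric(records$start) / 3600)
  one <- function(h) {
    ix <- key == h
    if (!any(ix)) NA_real_ else sum(records$index[ix])
  }
  c(sum_before = one(h0 - 1), sum_after_1 = one(h0 + 1),
    sum_after_2 = one(h0 + 2), sum_after_3 = one(h0 + 3))
}

#' Day-scale day/night activity series for one event
#'
#' For each labelled day (day before / day of / day after / second day
#' after) computes the mean of the hourly activity indices over the daytime
#' block and over the night block (18:00-05:59, attributed to the starting
#' date). A label with no recorded hours in a block is emitted as `NA` and
#' is later excluded from pairing for that event, mirroring the attrition
#' in the number of events available per comparison.
#'
#' @param event one-row event data.frame
#' @param hourly output of [hourly_mean_activity()]
#' @param scheme a [day_night_scheme()]
#' @return data.frame with `event_id`, `label`, `block`, `mean_activity`,
#'   `n_hours`
#' @export
day_scale_series <- function(event, hourly, scheme = day_night_scheme()) {
  days <- label_event_days(event)
  h <- as.POSIXlt(hourly$hour_start, tz = "UTC")$hour
  date <- as.Date(hourly$hour_start, tz = "UTC")
  night_date <- date
  night_date[h < 12] <- night_date[h < 12] - 1  # pre-dawn hours belong to previous night
  ok <- !is.na(hourly$maa_raw)
  rows <- list()
  for (lab in levels(days$label)) {
    dd <- days$date[days$label == lab]
    if (!length(dd)) next
    day_hours <- if (lab %in% c("day_of", "day_before"))
      scheme$day_of_day_hours else scheme$day_hours
    day_ix <- ok & date %in% dd & h %in% day_hours
    night_ix <- ok & night_date %in% dd & h %in% scheme$night_hours
    rows[[paste(lab, "day")]] <- data.frame(
      event_id = event$event_id, label = lab, block = "day",
      mean_activity = if (any(day_ix)) mean(hourly$maa_raw[day_ix]) else NA_real_,
      n_hours = sum(day_ix))
    rows[[paste(lab, "night")]] <- data.frame(
      event_id = event$event_id, label = lab, block = "night",
      mean_activity = if (any(night_ix)) mean(hourly$maa_raw[night_ix]) else NA_real_,
      n_hours = sum(night_ix))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Paired day-scale samples across events
#'
#' Matches each event's day-before value with its value at another day
#' label within a block, dropping events where either member is missing.
#'
#' @param series stacked output of [day_scale_series()] over events
#' @param label comparison label ("day_of", "day_after", "second_day_after")
#' @param block "day" or "night"
#' @return data.frame with `event_id`, `before`, `value`
#' @export
pair_with_baseline <- function(series, label, block = "day") {
  base <- series[series$label == "day_before" & series$block == block, ]
  comp <- series[series$label == label & series$block == block, ]
  m <- merge(base[, c("event_id", "mean_activity")],
             comp[, c("event_id", "mean_activity")],
             by = "event_id", suffixes = c("_before", "_comp"))
  m <- m[stats::complete.cases(m), ]
  data.frame(event_id = m$event_id, before = m$mean_activity_before,
             value = m$mean_activity_comp)
}
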