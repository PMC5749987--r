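#' Duty-cycle specification
#'
#' Describes a periodic recording schedule: the recorder is "on" for
#' `on_duration` seconds at the start of every `cycle_period`-second cycle,
#' with the cycle grid shifted by `offset` seconds. The monitoring programme
#' this package targets used 180 s of recording every 360 s (a 50% duty
#' cycle) at a 50 kHz sample rate; paired recorders were run at
#' complementary offsets so that one unit was always on.
#'
#' @param on_duration seconds recorded per cycle (default 180)
#' @param cycle_period cycle length in seconds (default 360)
#' @param offset shift of the cycle grid in seconds, in `[0, cycle_period)`
#' @return an object of class `duty_cycle`
#' @export
duty_cycle <- function(on_duration = 180, cycle_period = 360, offset = 0) {
  if (!(on_duration > 0 && on_duration <= cycle_period))
    stop("need 0 < on_duration <= cycle_period")
  if (offset < 0 || offset >= cycle_period)
    stop("offset must lie in [0, cycle_period)")
  structure(list(on_duration = on_duration, cycle_period = cycle_period,
                 offset = offset), class = "duty_cycle")
}

#' Build a duty-cycled recording schedule
#'
#' Enumerates the recording segments a duty-cycled recorder produces over a
#' deployment interval. Segment k starts at `start + offset + k * cycle_period`
#' and lasts `on_duration` seconds; only segments fully inside
#' `[start, end]` are returned. Timestamps are naive local time (represented
#' as UTC so that daylight-saving never shifts the clock).
#'
#' @param start,end POSIXct deployment bounds, `start < end`
#' @param duty a [duty_cycle()] object
#' @param site_id site label attached to every segment
#' @return data.frame with columns `site_id`, `start` (POSIXct),
#'   `duration_s`
#' @export
build_recording_schedule <- function(start, end, duty = duty_cycle(),
                                     site_id = "B") {
  start <- as.POSIXct(start, tz = "UTC")
  end <- as.POSIXct(end, tz = "UTC")
  if (!(start < end)) stop("invalid interval: end must be after start")
  t0 <- start + duty$offset
  span <- as.numeric(difftime(end, t0, units = "secs"))
  if (span < duty$on_duration)
    return(data.frame(site_id = character(0),
                      start = as.POSIXct(character(0), tz = "UTC"),
                      duration_s = numeric(0)))
  k_max <- floor((span - duty$on_duration) / duty$cycle_period)
  starts <- t0 + (0:k_max) * duty$cycle_period
  data.frame(site_id = site_id, start = starts,
             duration_s = duty$on_duration)
}

#' Fraction of a span covered by a schedule
#'
#' @param schedule data.frame from [build_recording_schedule()]
#' @param start,end span bounds
#' @return covered fraction in `[0, 1]`
#' @export
schedule_coverage <- function(schedule, start, end) {
  span <- as.numeric(difftime(as.POSIXct(end, tz = "UTC"),
                              as.POSIXct(start, tz = "UTC"), units = "secs"))
  sum(schedule$duration_s) / span
}

#' Write a schedule or counts table as CSV
#'
#' Timestamps are serialized as ISO 8601 (`start_iso8601`), the interchange
#' convention shared by every stage of the pipeline.
#'
#' @param x data.frame with a POSIXct `start` column
#' @param path output file
#' @export
write_segments_csv <- function(x, path) {
  out <- x
  out$start_iso8601 <- format(out$start, "%Y-%m-%dT%H:%M:%S")
  out$start <- NULL
  first <- c("site_id", "start_iso8601", "duration_s")
  out <- out[, c(first, setdiff(names(out), first)), drop = FALSE]
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read a segments/counts CSV written by [write_segments_csv()]
#' @param path CSV file
#' @return data.frame with POSIXct `start`
#' @export
read_segments_csv <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  x$start <- as.POSIXct(x$start_iso8601, format = "%Y-%m-%dT%H:%M:%S",
                        tz = "UTC")
  x$start_iso8601 <- NULL
  x
}
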