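#' Detonation-transient detector configuration
#'
#' The detector works on a short-window RMS envelope compared against a
#' running background estimate (trailing median of window RMS). An event is
#' triggered where the envelope exceeds the background by
#' `trigger_threshold` dB with a rise from background + `end_threshold` dB
#' to peak no slower than `max_rise_time` (the "near instantaneous" gate
#' that rejects ship-like ramps). The reverberation is over when the
#' envelope falls back below background + `end_threshold` dB, the same 6 dB
#' criterion used for the published size classes.
#'
#' @param rms_window envelope RMS window, s (default 10 ms)
#' @param background_window trailing background window, s (default 30 s)
#' @param trigger_threshold dB above background needed to trigger
#'   (default +20 dB)
#' @param max_rise_time maximum allowed rise time, s (default 50 ms)
#' @param end_threshold dB above background ending the reverberation
#'   (fixed at 6 dB by the size-class definition)
#' @param refractory events closer than this are merged, s
#' @return object of class `detector_config`
#' @export
detector_config <- function(rms_window = 0.01, background_window = 30,
                            trigger_threshold = 20, max_rise_time = 0.05,
                            end_threshold = 6, refractory = 5) {
  if (!(rms_window < background_window / 10))
    stop("rms_window must be much smaller than background_window")
  if (!(trigger_threshold > end_threshold))
    stop("trigger_threshold must exceed end_threshold")
  if (refractory <= 0) stop("refractory must be > 0")
  structure(list(rms_window = rms_window,
                 background_window = background_window,
                 trigger_threshold = trigger_threshold,
                 max_rise_time = max_rise_time,
                 end_threshold = end_threshold, refractory = refractory),
            class = "detector_config")
}

# Window-RMS envelope in dB and trailing-median background in dB.
# Returns a list with the window grid (window start times), envelope dB and
# background dB. The background at window i is the median of the envelope
# over the preceding `background_window` seconds (trailing, so a transient
# never inflates its own background estimate).
.envelope_db <- function(waveform, sample_rate, cfg) {
  win <- max(1L, round(cfg$rms_window * sample_rate))
  n_win <- floor(length(waveform) / win)
  if (n_win < 2) stop("insufficient context: waveform too short")
  m <- matrix(waveform[seq_len(n_win * win)]^2, nrow = win)
  rms <- sqrt(colMeans(m))
  db <- 20 * log10(pmax(rms, 1e-12))
  k <- max(3L, round(cfg$background_window / cfg$rms_window))
  if (k %% 2L == 0L) k <- k + 1L
  if (n_win > k) {
    bg <- zoo::rollmedian(db, k, align = "right", fill = NA)
    bg[seq_len(k - 1L)] <- bg[k]
  } else {
    bg <- rep(stats::median(db), n_win)
  }
  list(t = (seq_len(n_win) - 1L) * cfg$rms_window, db = db, bg = bg,
       win_s = cfg$rms_window)
}

#' Detect detonation transients in a waveform
#'
#' Searches the RMS envelope for excursions of at least
#' `trigger_threshold` dB above the running background with a near
#' instantaneous rise, merging triggers closer than the refractory period.
#' All thresholds are relative to the background estimate, so detection is
#' invariant to an overall gain change.
#'
#' @param waveform numeric samples (or output of [synthesize_waveform()])
#' @param sample_rate Hz; taken from the waveform attribute when omitted
#' @param cfg [detector_config()]
#' @return data.frame with one row per event: `onset_s`, `peak_db`
#'   (dB above background), `reverb_s`, `censored`, `size_class`
#' @export
detect_transients <- function(waveform, sample_rate = attr(waveform, "sample_rate"),
                              cfg = detector_config()) {
  if (is.null(sample_rate)) stop("sample_rate required")
  if (length(waveform) / sample_rate < cfg$background_window)
    stop("insufficient context: waveform shorter than background_window")
  env <- .envelope_db(waveform, sample_rate, cfg)
  exc <- env$db - env$bg
  hot <- which(exc >= cfg$trigger_threshold)
  empty <- data.frame(onset_s = numeric(0), peak_db = numeric(0),
                      reverb_s = numeric(0), censored = logical(0),
                      size_class = character(0))
  if (length(hot) == 0) return(empty)
  # group triggered windows separated by less than the refractory period
  gap <- c(Inf, diff(hot)) * env$win_s
  grp <- cumsum(gap >= cfg$refractory)
  out <- do.call(rbind, lapply(split(hot, grp), function(idx) {
    # rise time: from the last window below background + 6 dB to the first
    # window at or above the trigger threshold (the noisy burst envelope
    # can crest well after onset, so the gate anchors on the threshold
    # crossing, not the global peak)
    first_hot <- idx[1]
    before <- which(exc[seq_len(first_hot)] < cfg$end_threshold)
    rise <- if (length(before)) (first_hot - max(before)) * env$win_s else Inf
    if (rise > cfg$max_rise_time) return(NULL)
    onset_i <- idx[1]
    dur <- .reverb_from_envelope(env, exc, onset_i, cfg)
    data.frame(onset_s = env$t[onset_i], peak_db = max(exc[idx]),
               reverb_s = dur$duration, censored = dur$censored,
               size_class = classify_size(dur$duration))
  }))
  if (is.null(out)) return(empty)
  rownames(out) <- NULL
  out
}

# Reverberation duration from a precomputed envelope: first window at or
# after the onset where the excursion stays below end_threshold, relative to
# the frozen pre-onset background. Right-censored at the end of the record.
.reverb_from_envelope <- function(env, exc, onset_i, cfg) {
  bg0 <- env$bg[onset_i]  # background frozen at onset
  rel <- env$db - bg0
  after <- seq(onset_i, length(rel))
  below <- after[rel[after] < cfg$end_threshold]
  if (length(below) == 0)
    return(list(duration = (length(rel) - onset_i) * env$win_s,
                censored = TRUE))
  list(duration = (below[1] - onset_i) * env$win_s, censored = FALSE)
}

#' Measure reverberation duration for a known onset
#'
#' Time from the onset until the smoothed envelope falls back below the
#' pre-onset background + 6 dB. If the envelope never falls below the
#' threshold before the end of the recording the duration is right-censored
#' (flagged, duration = time to end of recording).
#'
#' @inheritParams detect_transients
#' @param onset_s onset time in seconds (from [detect_transients()])
#' @return list with `duration` (s) and `censored` (logical)
#' @export
measure_reverb_duration <- function(waveform,
                                    sample_rate = attr(waveform, "sample_rate"),
                                    onset_s, cfg = detector_config()) {
  env <- .envelope_db(waveform, sample_rate, cfg)
  onset_i <- max(1L, round(onset_s / env$win_s) + 1L)
  exc <- env$db - env$bg
  .reverb_from_envelope(env, exc, onset_i, cfg)
}

#' Classify a detonation by reverberation duration
#'
#' Small, medium and large detonations correspond to reverberation
#' durations of 0-2 s, 2-7 s and 7+ s. The printed bands overlap at their
#' boundaries, so the implementation uses the half-open partition
#' `[0, 2)`, `[2, 7)`, `[7, Inf)`.
#'
#' @param reverb_duration seconds, `>= 0`
#' @return character vector in `{"small", "medium", "large"}`
#' @export
classify_size <- function(reverb_duration) {
  if (any(reverb_duration < 0)) stop("parameter error: negative duration")
  as.character(cut(reverb_duration, breaks = c(0, 2, 7, Inf),
                   labels = c("small", "medium", "large"), right = FALSE))
}

#' Group detonations into training events
#'
#' Detonations on calendar days separated by at most `max_gap_days` belong
#' to the same training event (exercises span one to three consecutive
#' days). The event's "day of" is anchored to its first detonation day and
#' the after-days to its last.
#'
#' @param undets data.frame with a POSIXct `time` column, time-sorted
#' @param max_gap_days maximum calendar-day gap within one event (default 1)
#' @return list with `events` (event_id, first_undet_day, last_undet_day,
#'   n_undets) and `undets` (input with `training_event_id` appended)
#' @export
group_into_training_events <- function(undets, max_gap_days = 1) {
  if (nrow(undets) == 0)
    return(list(events = data.frame(event_id = integer(0),
                                    first_undet_day = as.Date(character(0)),
                                    last_undet_day = as.Date(character(0)),
                                    n_undets = integer(0)),
                undets = cbind(undets, training_event_id = integer(0))))
  stopifnot(!is.unsorted(undets$time))
  day <- as.Date(undets$time, tz = "UTC")
  gap <- c(0, as.numeric(diff(day)))
  id <- cumsum(gap > max_gap_days) + 1L
  events <- do.call(rbind, lapply(split(seq_along(id), id), function(ix)
    data.frame(event_id = id[ix[1]], first_undet_day = min(day[ix]),
               last_undet_day = max(day[ix]), n_undets = length(ix))))
  rownames(events) <- NULL
  undets$training_event_id <- id
  list(events = events, undets = undets)
}
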