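one_transient <- function(onset = 35, peak_db = 30, tau = 1, seed = 7,
                          duration = 60, sr = 4000) {
  synthesize_waveform(waveform_spec(sample_rate = sr, duration = duration,
                                    transients = data.frame(
                                      onset = onset, peak_db = peak_db,
                                      tau = tau), seed = seed))
}

test_that("stationary noise yields no events", {
  w <- synthesize_waveform(waveform_spec(duration = 60, seed = 3))
  expect_equal(nrow(detect_transients(w)), 0)
})

test_that("a single embedded transient is detected at its onset", {
  w <- one_transient(onset = 35)
  ev <- detect_transients(w)
  expect_equal(nrow(ev), 1)
  expect_lt(abs(ev$onset_s - 35), 2 * detector_config()$rms_window + 1e-9)
  expect_gt(ev$peak_db, 20)
})

test_that("reverberation duration matches the closed-form decay", {
  # envelope decays as exp(-t/tau); time to ambient + 6 dB is
  # ~ tau * ln(10^(30/20) / 10^(6/20)) = 2.763 tau
  for (tau in c(1, 3)) {
    w <- one_transient(onset = 30, peak_db = 30, tau = tau, seed = 21)
    ev <- detect_transients(w)
    expect_equal(nrow(ev), 1)
    expect_lt(abs(ev$reverb_s - 2.763 * tau) / (2.763 * tau), 0.10)
  }
  # tau = 3 -> ~8.3 s -> large
  w3 <- one_transient(onset = 20, peak_db = 30, tau = 3, seed = 21)
  expect_equal(detect_transients(w3)$size_class, "large")
})

test_that("an instantaneous return to background gives near-zero duration", {
  w <- one_transient(onset = 30, tau = 0.02, seed = 5)
  ev <- detect_transients(w)
  expect_equal(nrow(ev), 1)
  expect_lt(ev$reverb_s, 0.3)
})

test_that("a slow amplitude ramp is rejected by the rise-time gate", {
  set.seed(9)
  sr <- 4000
  t <- (0:(60 * sr - 1)) / sr
  gain <- 1 + ifelse(t > 30 & t < 40, (t - 30) / 10 * 30.6,
                     ifelse(t >= 40, 31.6, 0))
  x <- rnorm(length(t), sd = 0.01) * gain
  expect_equal(nrow(detect_transients(x, sr)), 0)
})

test_that("two transients ten seconds apart give exactly two events", {
  w <- synthesize_waveform(waveform_spec(
    sample_rate = 4000, duration = 60,
    transients = data.frame(onset = c(35, 45), peak_db = 30, tau = 1),
    seed = 5))
  ev <- detect_transients(w)
  expect_equal(nrow(ev), 2)
  expect_equal(ev$onset_s, c(35, 45), tolerance = 0.02)
})

test_that("detection is gain-invariant and translation-equivariant", {
  w <- one_transient(onset = 35, seed = 13)
  ev <- detect_transients(w)
  ev_gain <- detect_transients(10 * w, 4000)
  expect_equal(ev$onset_s, ev_gain$onset_s)
  expect_equal(ev$reverb_s, ev_gain$reverb_s)
  expect_equal(ev$size_class, ev_gain$size_class)
  # shift by an exact multiple of the RMS window
  k <- 2 * 4000 * 0.01
  set.seed(99)
  shifted <- c(rnorm(k, sd = 10^(-40 / 20)), as.numeric(w))
  ev_sh <- detect_transients(shifted, 4000)
  expect_equal(ev_sh$onset_s, ev$onset_s + k / 4000, tolerance = 1e-9)
})

test_that("a transient running into the end of the record is censored", {
  w <- one_transient(onset = 58, peak_db = 30, tau = 3, seed = 2)
  ev <- detect_transients(w)
  expect_equal(nrow(ev), 1)
  expect_true(ev$censored)
  expect_equal(ev$reverb_s, 2, tolerance = 0.1)
})

test_that("short waveforms are refused", {
  expect_error(detect_transients(rnorm(1000), 4000), "insufficient context")
})

test_that("size classes partition durations with half-open boundaries", {
  expect_equal(classify_size(c(0, 1, 1.999, 2, 5, 6.999, 7, 8, 100)),
               c("small", "small", "small", "medium", "medium", "medium",
                 "large", "large", "large"))
  expect_error(classify_size(-0.1), "negative")
  # idempotent/deterministic
  expect_equal(classify_size(2), classify_size(2))
})

test_that("detonations group into training events by calendar-day gaps", {
  u <- data.frame(time = as.POSIXct(c("2014-05-10 11:00", "2014-05-11 13:00",
                                      "2014-06-10 12:00"), tz = "UTC"))
  g <- group_into_training_events(u, max_gap_days = 1)
  expect_equal(nrow(g$events), 2)
  expect_equal(g$events$first_undet_day[1], as.Date("2014-05-10"))
  expect_equal(g$events$last_undet_day[1], as.Date("2014-05-11"))
  expect_equal(g$undets$training_event_id, c(1L, 1L, 2L))
  # single detonation: first == last
  g1 <- group_into_training_events(u[3, , drop = FALSE])
  expect_equal(g1$events$first_undet_day, g1$events$last_undet_day)
  # brute-force grouping oracle on random day patterns
  set.seed(4)
  for (i in 1:20) {
    days <- sort(sample(1:40, 8))
    uu <- data.frame(time = as.POSIXct("2014-01-01", tz = "UTC") +
                       days * 86400 + 3600)
    g <- group_into_training_events(uu, max_gap_days = 1)
    expected_breaks <- sum(diff(days) > 1)
    expect_equal(nrow(g$events), expected_breaks + 1)
  }
  # empty input
  expect_equal(nrow(group_into_training_events(
    data.frame(time = as.POSIXct(character(0))))$events), 0)
})

test_that("reverb duration can be measured for a supplied onset", {
  w <- one_transient(onset = 30, peak_db = 30, tau = 1, seed = 21)
  m <- measure_reverb_duration(w, onset_s = 30)
  expect_false(m$censored)
  expect_equal(m$duration, 2.763, tolerance = 0.1 * 2.763)
})
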