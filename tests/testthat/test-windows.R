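ev_row <- function(id, first, last = first) {
  data.frame(event_id = id, first_undet_day = as.Date(first),
             last_undet_day = as.Date(last))
}

test_that("event-day labels follow the first/last detonation rule", {
  d <- as.Date("2014-05-10")
  lab <- label_event_days(ev_row(1, d))
  expect_equal(lab$date, c(d - 1, d, d + 1, d + 2))
  expect_equal(as.character(lab$label),
               c("day_before", "day_of", "day_after", "second_day_after"))
  # two-day event: after-days anchor on the final detonation
  lab2 <- label_event_days(ev_row(1, d, d + 1))
  expect_equal(lab2$date[lab2$label == "day_after"], d + 2)
  expect_equal(lab2$date[lab2$label == "second_day_after"], d + 3)
  # three-day event spans 6 calendar days in total
  lab3 <- label_event_days(ev_row(1, d, d + 2))
  expect_equal(nrow(lab3), 6)
  expect_equal(sum(lab3$label == "day_of"), 3)
})

test_that("day labelling is a partition of the window", {
  lab <- label_event_days(ev_row(1, "2014-05-10", "2014-05-12"))
  expect_false(any(duplicated(lab$date)))
})

test_that("baseline eligibility requires 3 clean days before the event", {
  all_ev <- rbind(ev_row(1, "2014-05-01"), ev_row(2, "2014-05-10"))
  # previous event ended 2 days before -> ineligible
  prev2 <- rbind(ev_row(1, "2014-05-08"), ev_row(2, "2014-05-10"))
  expect_false(check_baseline_eligibility(prev2[2, ], prev2))
  # previous event ended 4 days before -> eligible
  expect_true(check_baseline_eligibility(all_ev[2, ], all_ev))
  # exactly 3 days before -> inside the window -> ineligible
  prev3 <- rbind(ev_row(1, "2014-05-07"), ev_row(2, "2014-05-10"))
  expect_false(check_baseline_eligibility(prev3[2, ], prev3))
  # first event with data present is eligible
  expect_true(check_baseline_eligibility(
    all_ev[1, ], all_ev[1, , drop = FALSE],
    recording_dates = seq(as.Date("2014-04-25"), as.Date("2014-05-05"),
                          by = "day")))
  # no recordings the day before -> ineligible
  expect_false(check_baseline_eligibility(
    all_ev[1, ], all_ev[1, , drop = FALSE],
    recording_dates = as.Date("2014-05-01")))
})

test_that("eligibility is monotone under added detonations", {
  base <- rbind(ev_row(1, "2014-04-20"), ev_row(2, "2014-05-10"))
  expect_true(check_baseline_eligibility(base[2, ], base))
  crowded <- rbind(base, ev_row(3, "2014-05-08"))
  expect_false(check_baseline_eligibility(crowded[2, ], crowded))
})

test_that("hour-scale windows sum whole clock hours around the detonation", {
  t0 <- as.POSIXct("2014-05-10 12:00:00", tz = "UTC")
  # 10 segments of index 2 in the hour before; 1 per following hour
  recs <- rbind(
    records_at(t0 + seq(0, by = 360, length.out = 10), rep(2, 10)),
    records_at(t0 + 2 * 3600 + c(0, 360), c(1, 0)),
    records_at(t0 + 3 * 3600, 10),
    records_at(t0 + 4 * 3600 + 1800, 10))
  undet <- as.POSIXct("2014-05-10 13:05:00", tz = "UTC")
  s <- hour_scale_windows(undet, recs)
  expect_equal(unname(s), c(20, 1, 10, 10))
  # all-zero hours give zero sums
  recs0 <- records_at(t0 + seq(-3600, 4 * 3600, by = 360), 0)
  expect_equal(unname(hour_scale_windows(undet, recs0)), c(0, 0, 0, 0))
})

test_that("missing clock hours propagate as NA, not zero", {
  t0 <- as.POSIXct("2014-05-10 12:00:00", tz = "UTC")
  recs <- records_at(t0 + c(0, 360), c(2, 2))
  s <- hour_scale_windows(as.POSIXct("2014-05-10 13:05:00", tz = "UTC"), recs)
  expect_equal(unname(s[1]), 4)
  expect_true(all(is.na(s[2:4])))
})

test_that("every clock hour belongs to exactly one day/night block and date", {
  hours <- seq(as.POSIXct("2014-05-09 00:00:00", tz = "UTC"),
               as.POSIXct("2014-05-12 23:00:00", tz = "UTC"), by = "hour")
  hourly <- data.frame(hour_start = hours, maa_raw = 1, maa = 0.25,
                       n_segments = 10)
  b <- day_block_means(hourly)
  expect_equal(sum(b$n_hours), length(hours))
  expect_false(any(duplicated(paste(b$date, b$block))))
  # full days contribute 12 hours to each block
  full <- b[b$date == as.Date("2014-05-10"), ]
  expect_equal(full$n_hours, c(12L, 12L))
})

test_that("a constant index yields constant day-scale means and zero diffs", {
  hours <- seq(as.POSIXct("2014-05-08 00:00:00", tz = "UTC"),
               as.POSIXct("2014-05-14 23:00:00", tz = "UTC"), by = "hour")
  hourly <- data.frame(hour_start = hours, maa_raw = 2.5, maa = 0.625,
                       n_segments = 10)
  ser <- day_scale_series(ev_row(1, "2014-05-10"), hourly)
  expect_true(all(ser$mean_activity == 2.5))
  p <- pair_with_baseline(ser, "day_of", "day")
  expect_equal(p$value - p$before, 0)
})

test_that("daytime-only suppression shows up in day means, not night means", {
  ev <- make_event_schedule(40, as.Date("2014-03-05"), spacing_days = 8)
  p <- activity_params(suppression = 0.3, seed = 31)
  st <- simulate_training_study(40, p, ev)
  ser <- do.call(rbind, lapply(seq_len(nrow(ev)), function(i)
    day_scale_series(ev[i, ], st$hourly)))
  day_p <- pair_with_baseline(ser, "day_of", "day")
  night_p <- pair_with_baseline(ser, "day_of", "night")
  expect_lt(mean(day_p$value), mean(day_p$before))
  d_night <- night_p$value - night_p$before
  expect_lt(abs(mean(d_night)), 3 * sd(d_night) / sqrt(length(d_night)))
})

test_that("the distant-site scheme restricts day-of daytime hours", {
  sch <- day_night_scheme("array_day_of")
  expect_equal(sch$day_of_day_hours, 10:17)
  expect_equal(sch$day_hours, 6:17)
  hours <- seq(as.POSIXct("2014-05-08 00:00:00", tz = "UTC"),
               as.POSIXct("2014-05-14 23:00:00", tz = "UTC"), by = "hour")
  hourly <- data.frame(hour_start = hours, maa_raw = 2, maa = 0.5,
                       n_segments = 10)
  ser <- day_scale_series(ev_row(1, "2014-05-10"), hourly, sch)
  expect_equal(ser$n_hours[ser$label == "day_of" & ser$block == "day"], 8L)
  expect_equal(ser$n_hours[ser$label == "day_after" & ser$block == "day"],
               12L)
})
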