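#!/usr/bin/env Rscript
# Stage 3 — occurrence and seasonality.
#
# Daily detections (recordings with any dolphin signal), monthly means with
# dispersion, and the percentage of monitored days with presence, from one
# simulated year at the default scene parameters.

suppressPackageStartupMessages(library(minexpam))
dir.create("results", showWarnings = FALSE)

sched <- build_recording_schedule(as.POSIXct("2014-01-01", tz = "UTC"),
                                  as.POSIXct("2015-01-01", tz = "UTC"))
records <- score_counts(simulate_counts(sched, activity_params(seed = 1)))
dailies <- daily_detections(records)
monthly <- monthly_summary(dailies)

utils::write.csv(dailies, "results/03_daily_detections.csv",
                 row.names = FALSE)
utils::write.csv(monthly, "results/03_monthly_summary.csv",
                 row.names = FALSE)

cat(sprintf("days with detections: %.1f%% of %d monitored days\n",
            percent_days_present(dailies), nrow(dailies)))
peak <- monthly$month[which.max(monthly$mean)]
trough <- monthly$month[which.min(monthly$mean)]
cat(sprintf("monthly detection means peak in month %d (%.0f/day) and\n",
            peak, max(monthly$mean)))
cat(sprintf("bottom out in month %d (%.0f/day), a %.0f%% reduction\n",
            trough, min(monthly$mean),
            100 * (1 - min(monthly$mean) / max(monthly$mean))))
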