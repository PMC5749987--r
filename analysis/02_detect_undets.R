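#!/usr/bin/env Rscript
# Stage 2 — detonation detection and size classing.
#
# Renders a set of synthetic recordings containing detonation transients of
# known reverberation time constants, runs the amplitude/rise-time detector
# and checks the measured reverberation durations against the closed-form
# envelope decay. Demonstrates the small/medium/large classification
# (reverberation 0-2 s / 2-7 s / 7+ s against the ambient + 6 dB criterion).

suppressPackageStartupMessages(library(minexpam))
dir.create("results", showWarnings = FALSE)

taus <- c(0.3, 0.8, 1.5, 2.2, 3.0)
rows <- list()
for (i in seq_along(taus)) {
  spec <- waveform_spec(sample_rate = 4000, duration = 60,
                        transients = data.frame(onset = 30, peak_db = 30,
                                                tau = taus[i]),
                        seed = 100 + i)
  ev <- detect_transients(synthesize_waveform(spec))
  ev$tau <- taus[i]
  ev$closed_form_s <- round(2.763 * taus[i], 2)
  rows[[i]] <- ev
}
events <- do.call(rbind, rows)
grouping <- group_into_training_events(
  data.frame(time = as.POSIXct("2014-05-10 11:00:00", tz = "UTC") +
               c(0, 3600, 86400 * 1, 86400 * 30)))

utils::write.csv(events, "results/02_undet_events.csv", row.names = FALSE)

cat("detected", nrow(events), "of", length(taus), "embedded transients\n")
print(events[, c("tau", "closed_form_s", "reverb_s", "size_class")],
      row.names = FALSE)
cat(sprintf("calendar-day grouping: 4 detonations -> %d training events\n",
            nrow(grouping$events)))
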