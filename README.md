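# minexpam

Passive-acoustic-monitoring (PAM) analysis of coastal dolphin responses to
underwater detonations (UNDETs) from naval mine-neutralization training,
implemented as a tested R package plus a set of numbered analysis drivers.

Bottom-moored recorders sample the soundscape for 180 s every 360 s (a 50%
duty cycle). Each 3-min recording is scored on an ordinal acoustic-activity
index (0–4 in steps of 0.5) from whistle abundance, burst-pulse abundance
and echolocation click rate; hourly means divided by 4 give the *mean
acoustic activity* (MAA) in [0, 1]. Around each training event (one to
three consecutive detonation days), activity on the day of and the days
after is paired with the day-before baseline and compared with a Wilcoxon
signed-rank test (effect size r = |Z|/√N) or a paired t-test (Cohen's
d = |t|/√n), gated by a Shapiro–Wilk normality check. MAA is also modelled
with a beta-regression GAM (logit link, thin-plate spline smooths) under
all-subsets AICc selection, and detonation exposure is summarized with the
shallow-water similitude relations

    peak pressure  p = 52.16e6 · (W^(1/3) / r)^1.13   [Pa]
    SEL            6.14·log10 W − 13.26·log10 r + A   [dB re 1 µPa²·s]

with A calibrated once, by least squares, to eight published reference
cells.

Because the original recordings are not publicly deposited, the package
includes a synthetic acoustic-scene generator (schedules, signal counts
with diel/seasonal/response structure, rendered waveforms with detonation
transients) so the full pipeline is exercised and validated end to end.
See `vignettes/minexpam-methods.Rmd` for the modelling details and design
choices.

## Worked example

```r
library(minexpam)

# a simulated study: 31 training events at a 50% duty cycle
params <- activity_params(seed = 1)          # suppression = 0.4 by default
events <- make_event_schedule(31)
study  <- simulate_training_study(31, params, events)

# day-scale paired comparisons vs the day-before baseline
series <- do.call(rbind, lapply(seq_len(nrow(events)), function(i)
  day_scale_series(events[i, ], study$hourly)))
day_scale_tests(series)[1, c("comparison", "block", "test", "statistic",
                             "p", "effect_size", "n")]
#>             comparison block     test statistic            p effect_size  n
#> 1 day_of_vs_day_before   day paired_t -9.220336 2.925793e-10    1.656021 31

# detonation detection on a rendered waveform (30 dB transient, tau = 1 s)
w <- synthesize_waveform(waveform_spec(
  sample_rate = 4000, duration = 60,
  transients = data.frame(onset = 35, peak_db = 30, tau = 1), seed = 7))
detect_transients(w)
#>   onset_s  peak_db reverb_s censored size_class
#> 1      35 31.93848     2.75    FALSE     medium

# sound exposure of a 20 lb charge at 12 km
round(sel_db(20, 12000))
#> [1] 173
```

The first result says the day-of daytime activity is strongly reduced
relative to baseline under the simulator's default 60% daytime
suppression (the normality gate picked the paired t-test here; Cohen's d
is reported); the detector measures a 2.75 s reverberation (analytic
expectation 2.76 s for tau = 1), a "medium" detonation; and a 20 lb charge
still delivers 173 dB re 1 µPa²·s at 12 km, which is why responses at
that range are plausible.

## Analysis drivers

`analysis/01_simulate_scene.R` … `06_propagation.R` run the stages in
order — scene simulation, detonation detection, occurrence/seasonality,
event-relative response tests, the beta GAM with model selection and
residual diagnostics, and the exposure table — each printing what it found
and writing its tables under `results/`.

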