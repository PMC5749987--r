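---
title: "Methods: passive acoustic monitoring of dolphin responses to underwater detonations"
author: "minexpam"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: passive acoustic monitoring of dolphin responses to underwater detonations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Naval mine-neutralization exercises detonate explosive charges in coastal
waters that coastal dolphins also use. A long-term way to ask whether the
animals react is passive acoustic monitoring: bottom-moored recorders
sample the soundscape on a duty cycle, analysts (or detectors) find the
detonations, and dolphin acoustic activity — whistles, burst pulses,
echolocation clicks — is compared before and after each training event.
`minexpam` implements that entire analysis chain as tested, reusable code:

1. duty-cycled recording schedules,
2. detection and size classing of underwater-detonation (UNDET)
   transients from waveforms,
3. an ordinal acoustic-activity index per 3-min recording, aggregated to
   hourly mean activity (MAA),
4. event-relative comparison windows at hour and day scales with paired
   response statistics and effect sizes,
5. a beta-regression GAM of normalized MAA with all-subsets AICc
   selection, and
6. a semi-empirical similitude model of detonation sound exposure.

No recordings from the original monitoring programme are publicly
deposited, so the package ships a synthetic acoustic-scene simulator that
reproduces the *structure* of those data — the recording schedule, diel
and seasonal signalling variation, and a suppression-and-recovery
response to detonations — and every downstream stage is validated against
it plus the published summary numbers.

# The synthetic scene

## What it emulates

The fielded recorders sampled 180 s every 360 s (a 50% duty cycle);
`build_recording_schedule()` reproduces exactly that grid, and all
timestamps are naive local clock time (daylight-saving is ignored, as the
original deployments set clocks at deployment time).

`simulate_counts()` draws, per 3-min segment:

* a Bernoulli **presence** indicator with probability
  `p = p_base(day/night) x diel_curve[hour] x seasonal_curve[month]`,
  clamped to [0, 1];
* given presence, **whistle** and **burst-pulse** counts from negative
  binomials (size = `dispersion`, default 1.5) and a **click rate** from a
  gamma law with occasional silence.

The default diel curve has a midday peak on top of mildly elevated night
rates, and the default seasonal curve peaks in October with a February
trough calibrated so that realized daily detections drop by roughly 90%
relative to the peak month — the published diel/seasonal pattern. No distribution for analyst whistle counts was
ever published; the negative-binomial choice is a stand-in (flagged as
such) justified only by the overdispersion typical of passive-acoustic
count data, and only the ordinal index consumes it downstream.

## The response mechanism

`suppression` (default 0.4) multiplies the **presence probability** during
daytime hours from the first detonation day through the end of the
suppression window (`suppression_hours`, default 48 h, i.e. the day of and
the day after the event); `rebound` (default 1.2) multiplies daytime
presence on the following day. Acting on presence rather than on
per-recording signal rates is a deliberate design choice with two
consequences:

* it encodes the favoured biological interpretation (animals leave the
  area rather than whistling less per group), and
* the expected value of every signal count scales *exactly* by the
  suppression factor, so the mean day-of/baseline daytime count ratio
  equals `suppression` in law — a property the tests verify by Monte
  Carlo — while still propagating through the banded activity index
  (a rate-only multiplier can leave the index unchanged whenever counts
  stay inside one band).

The default suppression of 0.4 (a 60% daytime reduction) is the effect
size at which the power properties of the pipeline are assessed with
n = 31 events, the number of training events the original site-B analysis
had.

## What it does not emulate

Presence is drawn independently per segment: real dolphin groups persist
across consecutive recordings, so real counts are serially correlated
within hours. Whistle contours, species-specific click spectra and ocean
propagation are not synthesized. Passing tests therefore demonstrate that
the *pipeline* is correct and well-calibrated under a plausible data
model, not that the simulator is a faithful model of any particular wild
population.

# Detonation detection

The detector computes a short-window RMS envelope (10 ms windows) and a
running background as the **trailing median** of the envelope over the
preceding 30 s — trailing, so a transient never inflates its own
background; median, so the estimate is robust to the transient's tail. An
event triggers where the envelope exceeds background by 20 dB, with a
rise-time gate: the excursion must climb from background + 6 dB to the
trigger level within 50 ms ("near instantaneous"), which rejects
ship-passage ramps. Triggers closer than a 5-s refractory period merge.

Reverberation duration runs from onset until the envelope first falls
below background + 6 dB (background frozen at onset); if that never
happens before the record ends, the duration is right-censored and
retained with a flag (class from the censored duration as a lower bound)
rather than dropped. Size classes are the half-open partition
[0, 2) / [2, 7) / [7, Inf) seconds — the published bands overlap at their
edges, and half-open intervals make the map a total partition. None of
the window sizes or thresholds were published; the defaults here are
engineering choices validated on synthetic fixtures (recall 1.00, zero
false positives over 100 embedded transients at peaks >= +20 dB), and all
are exposed in `detector_config()`.

An analytic oracle anchors the duration measurement: for an exponential
reverberation tail of time constant tau starting 30 dB above ambient, the
envelope crosses ambient + 6 dB after approximately `tau * ln(10^(30/20) /
10^(6/20)) = 2.763 tau` seconds (slightly less when ambient noise power is
accounted for); the detector's measured durations agree within 10%.

# The activity index and MAA

`score_recording()` encodes the published 9-level ordinal index
{0, 1, 1.5, 2, 2.5, 3, 3.5, 4} from whistle abundance bands, burst-pulse
abundance and click rate. The printed band edges leave 41 whistles and
exactly 10 burst pulses unassigned; the implementation closes the upper
bands (1-20 / 21-40 / >= 41 whistles; < 10 / >= 10 burst pulses;
< 2 / >= 2 clicks/s), a convention isolated in one table-driven function
and verified against an independent brute-force encoding over the
exhaustive lattice of counts up to 60 whistles x 20 burst pulses x
{0, 1, 3} clicks/s, including monotonicity in every argument.

Hourly mean activity is the mean index over the segments starting within
each clock hour, divided by 4 to lie in [0, 1]. Hours without segments are
missing, never zero — index 0 is a valid observation ("no signals"), so
imputing zeros would bias every downstream comparison.

# Event-relative windows

Day labels anchor on the training event: day before = first detonation
day − 1; day of = every day carrying detonations; day after and second
day after follow the *final* detonation. Events without a clean 3-day
pre-event baseline are excluded. Hour-scale comparisons use whole clock
hours (the hour before a detonation's clock hour vs each of the three
following hours), matching the hourly grid of the day-scale analysis.
Daytime is the fixed block 06:00-17:59 and night 18:00-05:59; the night
block spans midnight and is attributed to the date it starts on, keeping
each label's night contiguous. The distant-site variant restricts the
day-of daytime block to 10:00-17:59 (the window containing >90% of
detonations), with the matched baseline block restricted identically.

# Response statistics

Paired comparisons of each label against the day before use either a
paired t-test or a Wilcoxon signed-rank test, gated by a Shapiro-Wilk
normality test on the differences at alpha = 0.05 (the original analysis
named no procedure; Shapiro-Wilk is the standard small-sample choice).
The Wilcoxon implementation reports the tie-corrected
normal-approximation Z without continuity correction, switching to the
exact signed-rank distribution when at most 15 untied pairs remain; zero
differences are dropped before ranking (the classic treatment — the
Pratt alternative changes Z, which is why the choice is documented).
Effect sizes follow the conventions used in this literature:
r = |Z|/sqrt(N) with N the number of pairs, and Cohen's
d = |t|/sqrt(n). The 30-s whistle-count comparison is the one analysis
that demonstrably used the total-observations denominator
r = |Z|/sqrt(2N); both conventions are implemented and every result is
labelled with the convention used rather than silently harmonized.

Operating characteristics are part of the acceptance surface: under a
null simulation (suppression = 1) the day-scale Wilcoxon pipeline rejects
at 0.046 over 500 replicates (inside the binomial 95% interval around
0.05), and at suppression = 0.4 with 31 events its power exceeds 0.80.

# The beta-regression GAM

Normalized MAA lives in [0, 1] with many exact zeros, so the response is
squeezed once, globally, by `y' = (y (n - 1) + 1/2) / n` before any fit
(the standard shrink-toward-1/2 transform; 1/2 is a fixed point and the
transform is invertible). Fits use a beta likelihood with logit mean link
and penalized thin-plate regression splines for the continuous predictors
(hour of day, hours since explosion, cumulative hours; basis dimension 10,
non-cyclic — the published hour effect is visibly non-cyclic), categorical
predictors as factors and ordinal ones linearly. Estimation goes through
`mgcv::gam(family = betar)` with REML smoothness selection — the standard
estimator for this model family. Model ranking uses
`AICc = -2 logLik + 2k + 2k(k+1)/(n-k-1)` with `k = sum of effective
degrees of freedom + 1` for the beta precision, enumerated over **all
subsets** of the candidate predictors (intercept always included); among
AICc ties at 2 decimal places the model with fewest predictors is
selected. Per-predictor explained-deviance contributions come from
refitting the selected model without each predictor in turn; they are
reported individually and need not sum to the full model's explained
deviance.

Residual autocorrelation is assessed with the sample acf to lag 48 and
the Durbin-Watson statistic `DW = sum((e_t - e_{t-1})^2) / sum(e_t^2)`,
with a permutation p-value (>= 2000 permutations of the residual order):
the classical tabulated DW bounds assume ordinary linear regression and do
not apply to a penalized beta GAM.

Validation is by parameter recovery at desk scale, sizes chosen once as
realistic for the structure being recovered: a known diel smooth through
the logit link is recovered with correlation >= 0.95 and the precision
parameter within 20% at n = 5000, phi = 20; all-subsets selection over
{hour (smooth), day, season} with truth {hour, day} at strong effects
picks a subset containing the truth in >= 90% of 100 replicates at
n = 1000 rows per replicate. An intercept-only fit is cross-checked
against a brute-force grid maximization of the beta log-likelihood, a
route independent of mgcv.

# Sound-exposure propagation

Peak pressure uses the shallow-water similitude form
`p = 52.16e6 (W^(1/3)/r)^1.13` Pa and SEL the form
`6.14 log10 W - 13.26 log10 r + A` dB re 1 uPa^2 s, with the additive
constant A calibrated once by least squares to the eight published
reference cells (5 lb and 20 lb charges at 1/3/6/12 km). The calibration
reproduces every SEL cell within 0.39 dB and every peak-pressure cell
within 0.5%, and gives 173 dB for a 20 lb charge at 12 km. Back-solving
the cells shows they are consistent with the *as-printed* nominal charge
weights entering the formulas directly — not with a kg-TNT conversion at
any standard equivalence factor, although such a conversion is nominally
implied — so `weight` is treated as the as-printed value by default and a
`lb_c4_to_kg_tnt()` helper is provided for physically explicit use. This
unit ambiguity is surfaced in the documentation rather than resolved.

# Numerical and design notes

* **Seeding.** One integer master seed; each simulator operation derives
  its own stream by a fixed offset (counts +1, waveforms +2, whistle
  pairs +3). Identical seeds give bit-identical outputs, hash-checked in
  the pipeline tests.
* **Degenerate inputs.** Empty schedules yield empty outputs; all-zero
  paired differences yield a flagged degenerate result with p = 1;
  zero-variance differences with nonzero mean flag an infinite t;
  constant responses shrink the GAM smooths toward their unpenalized
  null space (the thin-plate linear part is never penalized, so one to
  two effective df is the floor) with explained deviance near 0.
* **Problem sizes.** Simulation-based checks use one simulated year
  (87,600 segments) for occurrence properties, 500/200 replicates of a
  ~340-day study for the type-I/power characteristics, 100 rendered
  60-s recordings at 4 kHz for detector recall, and the GAM sizes above —
  sizes chosen as the package's own desk-scale study conditions.
* **Interchange.** Stages communicate through plain CSV (ISO 8601
  timestamps, index written with one decimal so the .5 levels survive)
  and mono PCM WAV; a minimal 16/24-bit RIFF reader/writer is included.

# Known limitations

The simulator's independence assumptions understate serial correlation in
real counts, so the type-I calibration shown here does not guarantee
calibration on field data with strong within-day persistence. The
detector's defaults were never reconciled against the original analysts'
manual picks (no such comparison was published). The GAM acceptance
surface is recovery on simulated data; the published deviance table
cannot be reproduced without the original 27,816-hour dataset and is not
attempted.
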