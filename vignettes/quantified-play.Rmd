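---
title: "Quantifying object play from an instrumented ball: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying object play from an instrumented ball: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement problem

Service-dog programs release a substantial fraction of candidate dogs for
temperament reasons, after months of expensive training. One promising,
low-burden way to quantify temperament is instrumented play: a silicone
ball carrying a barometric pressure sensor and a 9-axis IMU records how a
dog mouths and retrieves it. When the dog bites, the internal air
pressure rises above ambient; the pressure trace therefore encodes the
timing, strength (as a pressure proxy, in kPa, not a calibrated force)
and rhythm of every bite. Trials come in two conditions — the ball rolled
by a person ("human") or released down a PVC ramp ("ramp") — because a
dog's play changes when a human participates.

`toysense` implements the full analysis path for this kind of study:

1. a **synthetic cohort generator** producing raw sensor streams with a
   ground-truth log of every injected bite,
2. **stream I/O**, magnet-sync detection and trial segmentation,
3. rule-based **bite detection** and per-trial feature engineering,
4. collinearity **pruning** and condition-by-outcome summaries,
5. a binomial **GLM** of placement outcome with adjusted odds ratios and
   estimated-marginal-mean likelihood curves, and
6. a Cohen f² **power analysis** plus the classification-metric
   conventions used for individual-feature predictors.

Because raw study data of this kind is typically not shareable, the
generator is a first-class, tested component: it defines the study
conditions everything downstream is validated against.

## The synthetic cohort

The packaged design (`cci_study.yaml`) encodes a 48-dog cohort: 30 dogs
placed across five service roles, 10 released for behavioral reasons,
and 8 removed from analysis (medical release, breeders, diabetic-alert
placement). Each dog runs 10 trials per condition — 960 trials, of which
160 belong to excluded dogs, leaving 800 analyzable rows and a 75%
placement rate among the 40 analyzable dogs. Exactly 41 ramp and 36
human trials are injected as *zero-interaction* trials (the dog never
touches the ball); these are all-zero feature rows, assigned by a seeded
draw among analyzable dogs' trials so the pipeline's recovery of the
counts is deterministic.

Per-trial plans are drawn per placement class and condition:

* **bite count**: 1 + Poisson(λ), truncated to a configured range;
* **bite duration**: truncated lognormal (ramp means ≈ 0.19–0.24 s,
  upper bounds 0.34–2.7 s depending on class);
* **bite peak pressure**: truncated normal, 105.5–258 kPa around class
  means of 107–112 kPa, over a 101.5 kPa baseline;
* **interaction time**: truncated lognormal, means ≈ 8–12 s with tails
  to ~200 s.

Truncated draws use inverse-CDF sampling, so they are exact and
reproducible. Placed dogs draw slightly *shorter* mean bite durations
than released dogs; the direction follows the adjusted (conditional)
duration effect rather than the marginal per-class summaries, and the
magnitude is configurable. Bites are laid out sequentially with
inter-bite gaps of at least 0.12 s plus a term proportional to the
preceding bite's duration, which bounds the local pulse duty cycle near
40% — a property the detector's baseline estimate relies on (below).

Each planned bite becomes a smooth pulse: half-sine rise and fall edges
(capped at 0.02 s) around a flat plateau at the planned peak, aligned to
the sample grid. The cap makes every pulse sample exceed the detection
threshold for peaks ≥ 4 kPa over baseline, so a correctly estimated
baseline recovers the planned duration to the sample. Pressure noise is
Gaussian (σ = 0.05 kPa); a slow sinusoidal barometric drift is available
but off by default. The magnetometer carries a hard-iron offset, noise,
and a ~400 µT swipe near each end of the stream, emulating the magnet
sync gesture; the gyroscope gets a decaying roll signature.

What the generator deliberately does **not** emulate: sub-ambient
pressure readings (observed minima near 60 kPa in real data have no
documented mechanism; detection assumes positive deviations), sensor
dropouts, saliva/temperature effects on the barometer, dog-specific
idiosyncrasy beyond the class distributions, and any within-session
carry-over between trials. Passing recovery tests on this cohort shows
the pipeline is internally consistent — not that the detector would be
100% sensitive on real hardware.

## Bite detection and features

The detector is the transparent rule the features are defined by: a bite
is a maximal run of samples with pressure ≥ baseline + 2 kPa, after
merging runs separated by less than 0.05 s and discarding runs shorter
than 0.01 s. The baseline is a rolling median, robust to pulses
occupying less than half its window and able to track slow drift.

Two numerical choices matter here:

* **Baseline window, 10 s.** A rolling median only ignores bites while
  they occupy under half the window. With plausible bite durations up to
  ~2.7 s, a 2 s window can sit entirely inside one sustained bite and
  lift the baseline onto the pulse plateau, splitting or missing events;
  10 s keeps worst-case local occupancy (bounded by the generator's gap
  rule, and in practice by dogs needing to reposition their jaws) safely
  below one half. The window is configurable for instruments with faster
  drift.
* **Endrule, constant.** Near the ends of a stream a shrinking median
  window would again be dominated by an early or late bite; the
  first/last full-window median is extended to the edges instead. The
  cost is that drift within the first/last half-window is flattened —
  negligible at the default drift rates.

Per trial, the features are: interaction time (annotated retrieval time,
falling back to the last event offset), number of bites, the
average/max/total of bite strength (peak pressure), duration, and RMS
pressure, average bite frequency (bites per trial second), and peak bite
frequency. Peak bite frequency is defined here as the reciprocal of the
smallest inter-onset interval (falling back to n/T below two bites),
which is the only reading on which per-trial values of ~100 bites/s are
possible; the session-level n/T alternative is selectable
(`peak_freq_method = "per_trial"`). A trial with no events is an
all-zero row flagged `zero_interaction`.

## Model, odds ratios, marginal means

Placement (1 = placed, 0 = behavioral release) is modeled by a binomial
GLM with logit link on five covariates — average bite duration, average
bite strength, interaction time, peak bite frequency, and condition
(treatment-coded, ramp reference) — retained by correlation pruning from
the full feature set. Pruning is a deterministic greedy rule (drop the
member of the worst |r| > 0.7 pair with the larger mean |r|,
lexicographic tie-break) with the model covariates pinned, replacing
subjective heatmap inspection. Pearson correlation is the default;
covariates enter on their raw scales, so odds ratios are per second, per
kPa, per bite/s.

Trials are pooled across dogs with no dog-level random effect. This
mirrors the source design but is pseudo-replication: 20 trials per dog
are not independent, so intervals are anti-conservative with respect to
dog-level inference. A mixed model is a deliberate non-goal here;
results should be read as trial-level associations. Zero-interaction
rows are included in the fit and in covariate means.

Fitting is IRLS (`glm`, tolerance 1e-8, ≤ 100 iterations). Degenerate
responses error before fitting; perfect separation is detected from the
saturation warning plus a diverging coefficient and errors with the
separating covariate named. Adjusted odds ratios are `exp(β)` with 95%
profile-likelihood intervals by default (asymmetric, appropriate for
small effective samples; Wald selectable). Estimated-marginal-mean
curves sweep one covariate over its observed range with the others at
their sample means and condition fixed; the band is the delta-method
standard error on the linear predictor mapped through the inverse logit,
so it is contained in [0, 1] by construction. Whether marginal means
should use covariate means or a reference grid is genuinely open; means
over all rows (zeros included) were chosen to match how the zero trials
are treated in the fit, and `emmeans` reproduces the curves exactly at
the covariate means (this identity is a test).

## Power analysis and metrics

`required_sample_size()` solves the limiting noncentral chi-square power
equation: find λ such that a χ²(u) test at level α has the target power,
then N = ⌊λ/f²⌋. For u = 5, f² = 0.02, α = 0.05, power 0.80 this gives
λ ≈ 12.83 and N = 641, i.e. 33 dogs at 20 observations per dog
(`dogs_needed()`, ceiling). The λ/f² convention is used rather than the
noncentral-F iteration with N = u + v + 1 (which gives ≈ 647) because
the chi-square limit is the natural large-sample reference for a GLM;
`achieved_power()` closes the loop and the round trip is tested to
0.5%. An α of 0.5 is treated as nonsensical for design purposes; 0.05
is the design default.

`classification_metrics()` fixes the conventions for individual-feature
predictor evaluation: accuracy; support-weighted one-vs-rest precision,
recall and F (a class with no predicted positives contributes precision
0 — this is the convention under which a constant-positive predictor on
a 75/25 split scores precision 0.5625 and F 0.6429); MCC with a zero
denominator defined as 0; AUC as the Mann–Whitney rank statistic with
midrank (half) credit for ties.

## Problem sizes and determinism

The validation suite runs the full 960-trial cohort once (about half a
minute), checks detector-vs-oracle equivalence on 1,000 randomized short
trials, estimates CI coverage from 200 replicates of 250 trials, and
uses 10,000-row simulations for coefficient recovery — sizes chosen so
the whole suite completes in a few minutes while keeping Monte-Carlo
error well inside the asserted tolerances. Every stochastic step is
driven by an explicit seed; the cohort generator consumes a single
seeded RNG stream in a fixed trial order, so identical configurations
give byte-identical outputs. The injected zero-interaction counts are
exact by construction, so their recovery is seed-invariant as long as
the detector produces neither false positives (threshold is 40 noise
SDs) nor false negatives (peaks are ≥ 4 kPa over baseline).

## Known limitations

* Pressure-to-force calibration is out of scope; "bite strength" is a
  pressure proxy.
* No dog-level random effects (see above).
* The detector assumes positive pressure deviations; a sensor that can
  read below ambient during play would need a two-sided rule.
* The generator's class separation is mild and configurable; the GLM's
  fitted effect sizes on the default cohort are not calibrated to any
  published estimate, and only the *recovery* properties (ground-truth
  bites, injected zero counts, simulated coefficients) are asserted.
* IMU channels are carried and synthesized but no IMU-derived behavior
  features (e.g. shake/"kill" gestures) are implemented.
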