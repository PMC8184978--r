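---
title: "Early-warning signals and rhythm stability from actigraphy: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Early-warning signals and rhythm stability from actigraphy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bdews)
```

## The problem and the model

Mood episodes in bipolar-I disorder — manias and depressions — are
transitions between states of a complex system. If those transitions behave
like tipping points, critical slowing down should precede them: the system
recovers more slowly from perturbations, which shows up in its observable
output as rising variance, rising autocorrelation and a changing
distribution shape (kurtosis). Minute-epoch wrist actigraphy is an
attractive observable because it is objective, continuous over months, and
directly reflects the psychomotor and sleep/wake disturbances that
characterise the disorder.

`bdews` operationalises this idea as a fixed pipeline:

1. **Episode definition.** Weekly ASRM and IDS-SR questionnaires define
   onsets: ASRM > 5 for ≥ 2 consecutive weeks (manic), IDS-SR > 25 for
   ≥ 3 consecutive weeks (depressive). Thresholds are strict and missing
   weeks break runs; the first qualifying run of either type is the
   patient's transition, dated to the first day of its first week (weekly
   assessments give no finer resolution).
2. **Detrending.** A single ordinary-least-squares line (time in minutes as
   regressor, fitted on observed epochs) is removed from the whole series
   before windowing. Variance, kurtosis and autocorrelation are all
   sensitive to slow drift; removing the global trend once keeps windows
   comparable. Per-window detrending would remove part of the signal the
   trend test is meant to find.
3. **Windowing.** Rolling windows of 7 days (10,080 one-minute epochs)
   advanced by 1 day, so every window contains at least one full weekend.
   Only full windows are emitted. A window is labelled by the day it *ends*,
   so the indicator dated day *d* uses only data observed before *d* — the
   causal labelling a prospective monitor would need — and a 4-week
   pre-onset span yields n = 28 daily values.
4. **Indicators.** Per window: sample variance (denominator n−1), Pearson
   raw kurtosis m₄/m₂² (moment denominator n), and the lag-720
   autocorrelation with the full-window mean and pairwise-complete products.
   Raw rather than excess kurtosis follows the resilience-indicator
   convention; the two differ by a constant shift, to which the rank-based
   trend test is insensitive.
5. **Trend testing.** The Mann-Kendall test on the ≤ 28 pre-onset indicator
   values, with tie-corrected variance and continuity correction, two-sided.
   Direction is derived strictly from the sign of S. Two-sidedness matters:
   empirically the autocorrelation indicator moves in either direction
   before episodes.
6. **Group pooling.** Fisher's method per indicator across patients,
   χ² = −2Σln pᵢ on 2k degrees of freedom.
7. **Rhythm stability.** Per 7-day window of *raw* counts (mean-removed):
   an unsmoothed FFT periodogram; the power at the 24-h fundamental
   (bin k = 7 of a 10,080-point window) and harmonics n = 2..6; the
   harmonic ratio P(12 h)/P(24 h). A `WARN` event fires when the ratio
   first reaches 0.9, a `SWITCH` when the dominant candidate period first
   leaves 1440 min. The candidate set {1440/n, n ≤ 6} covers the observed
   12-h and 4-h phenomena while excluding leakage-prone long periods;
   sub-fundamental (48-h) rhythms are out of scope.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| window length | 10080 | min | 7 days: weekend balance; puts 1/1440 exactly on FFT bin 7 |
| step | 1440 | min | daily indicator resolution |
| `min_completeness` | 0.9 | fraction | windows with >10% missing epochs are unusable; no imputation |
| lag | 720 | min | 12 h: day/night contrast |
| pre-onset span | 28 | days | plausible horizon for EWS growth; n = 28 trend values |
| alpha | 0.05 | — | significance is p ≤ alpha, two-sided |
| `warn_threshold` | 0.9 | ratio | harmonic ratio approaching 1 signals an imminent switch |
| `switch_threshold` | 1.0 | ratio | fallback switch rule when only ratios are available |

Missing data: indicators use only observed epochs (masked computation equals
deletion); the periodogram, which cannot mask, fills missing epochs with the
window mean, which adds no spectral power. The completeness rule (0.9) is an
implementation choice — no published missingness rule exists for this
design.

## The synthetic generator

Real patient actigraphy for this design is not publicly deposited, so the
package ships a generator whose output has the statistical structure the
analysis assumes:

- **cosinor mean curve** `mesor + amplitude·cos(2π(t − 720)/1440)` (trough
  at midnight, peak at noon) with additive Gaussian epoch noise, truncated
  at zero. Defaults: 180 days, mesor 100, amplitude 100, noise sd 25 count
  units — six months of counts spanning ~0 at night to ~200 at midday,
  matching the magnitude of published weekly means (≈50–190 counts), with
  the noise at a quarter of the amplitude so the 24-h peak dominates the
  spectrum.
- **variance ramp**: the noise sd rises linearly to `variance_gain ×`
  baseline over the `ramp_days` before onset (default gain 4 over 28 days)
  and stays there — the monotone alternative the Mann-Kendall test targets.
  Truncation at zero makes the count distribution's shape change alongside,
  so kurtosis and acf-720 also respond, as they do in patients.
- **rhythm switch**: from `switch_day` the 24-h cosine is replaced by one of
  the target period (e.g. 720 or 240 min) at the same amplitude —
  a controllable version of the observed 24-h→12-h deregulation.
- **symptom series**: baseline ASRM 0–3 and IDS-SR 8–20 (never satisfying
  either criterion); from the onset week, ASRM 7–14 or IDS-SR 28–45.

Injection re-synthesises the series deterministically from the stored
parameters and seed, so a signature that changes nothing reproduces the
input bit for bit, and pre-ramp counts are always unchanged.

What the generator does *not* emulate: sleep architecture and naps,
weekday/weekend structure, medication effects, off-wrist missingness
patterns, and the autocorrelated intra-day dynamics of real movement
(epoch noise is independent). Passing the calibration tests therefore shows
the pipeline detects the modelled signatures at realistic effect sizes — it
does not certify sensitivity or specificity on real patients.

## Numerical and design choices

- **Mann-Kendall**: tau is classical tau-a, consistent with published
  per-patient tables (tau 0.444 at n = 28 gives S = 168 and a no-ties z of
  3.299, within 1% of the printed 3.319); the continuity correction makes
  p = 1 exact at S = 0; all-tied series return S = 0, z = 0, p = 1 rather
  than an error.
- **Fisher's method** is implemented in its standard χ²(2k) form.
- **Direction vs. printed tables**: some published kurtosis rows pair a
  negative z with the label "increase"; `bdews` derives direction from
  sign(S) only, so those rows disagree by design.
- **Harmonic ratio degenerate case**: when fundamental power is below
  10⁻¹² of total power the ratio is reported as `Inf` (a pure 12-h rhythm),
  never 0/0.
- **Rolling-window overlap** inflates trend-test rejection on null data
  because consecutive indicator values share 6/7 of their epochs. The
  size calibration therefore uses *non-overlapping* windows (step = window
  length), where the Mann-Kendall rejection rate on synthetic null patients
  is near the nominal 5%. Pre-onset p-values from overlapping windows
  should be read as descriptive rankings, not calibrated error rates — the
  published design shares this caveat, and block-bootstrap nulls are out of
  scope here because strong daily periodicity defeats standard bootstraps.
- **Mean-activity comparisons** use raw (never detrended) counts: the
  euthymic reference is the first 7 days of the euthymic interval, the
  pre-onset period the 7 days ending at onset, the during-episode period
  the first 7 days from onset.
- **Same-week tie** between manic and depressive criteria is refused with
  an error rather than silently resolved; weekly instruments cannot
  adjudicate it.

## Problem sizes used in the shipped checks

Calibration runs use 56-day series (onset day 35: exactly 28 pre-onset
indicator days) for power — 100 seeds — and 180-day series for null
behaviour: 1,000 seeds for the non-overlapping-window size check (tests) or
500 in the acceptance script, 20,000 replicates for the Gaussian type-I
rate at n = 28, and 5 seeds for rhythm false alarms. These sizes give
Monte-Carlo standard errors well inside the tolerance bands they are
checked against.

## Known limitations

- Weekly symptom granularity dates onsets no finer than the week.
- Daylight-saving shifts are not modelled; wall-clock duplicate or absent
  epochs are rejected at ingest.
- The spectral window (7 days) is a package choice; daily-resolved ratio
  series from shorter windows would trade frequency resolution for timing
  precision.
- No false-positive-rate study on long euthymic-only spans is shipped; the
  null generator makes one straightforward to run.
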