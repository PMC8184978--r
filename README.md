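# bdews — early-warning signals from actigraphy for bipolar mood transitions

Patients with bipolar-I disorder cycle between euthymic periods and manic or
depressive episodes. Complex-systems theory predicts that, near a tipping
point, a system shows *critical slowing down*, detectable as rising variance,
autocorrelation and kurtosis in its output — generic early-warning signals
(EWS). `bdews` implements a complete, tested pipeline that looks for these
signals in continuous wrist-actigraphy recordings (1-minute epoch activity
counts over ~180 days) in the four weeks before a mood-episode onset, for
researchers working on digital phenotyping and relapse prediction.

## What it computes

For each patient, on the globally detrended minute-level series, in rolling
7-day windows advanced by 1 day:

- **variance** — sample variance `s² = Σ(xᵢ − x̄)²/(n−1)` per window;
- **kurtosis** — Pearson (raw) kurtosis `m₄/m₂²` with moments of denominator
  `n`; Gaussian reference 3, lower bound 1;
- **acf-720** — autocorrelation at lag 720 min (12 h),
  `Σₜ(xₜ − x̄)(xₜ₊₇₂₀ − x̄) / Σₜ(xₜ − x̄)²` over valid pairs: near −1 for a
  strong 24-h rhythm, drifting toward 0 or above when the sleep/wake cycle
  deregulates.

The daily indicator values inside the 4-week pre-onset interval are tested
for a monotonic trend with the **Mann-Kendall test** (pair-sign sum
`S = Σ_{i<j} sign(xⱼ − xᵢ)`, ties-corrected variance
`Var(S) = [n(n−1)(2n+5) − Σₜ t(t−1)(2t+5)]/18`, continuity-corrected normal
deviate, two-sided p, tau-a `= S / (n(n−1)/2)`), and per-patient p-values are
pooled per indicator with **Fisher's method** `χ² = −2Σ ln pᵢ ~ χ²(2k)`.

In parallel, an **unsmoothed FFT periodogram** of each 7-day window of raw
counts yields the power at the 24-h fundamental and its harmonics; the
**harmonic ratio** (12-h power / 24-h power) approaching or exceeding 1 flags
a switch away from the normal circadian rhythm (`WARN`/`SWITCH` events).

Episode onsets come from weekly questionnaires: ASRM > 5 for 2 consecutive
weeks (manic) or IDS-SR > 25 for 3 consecutive weeks (depressive).

A seeded synthetic generator (cosinor mean curve + truncated Gaussian noise,
with injectable pre-onset variance ramps and rhythm switches) stands in for
patient data and calibrates power and false-alarm behaviour.

## Worked example

Simulate a patient whose depressive episode at day 35 is preceded by a
4-fold noise ramp over 28 days, then analyse:

```r
library(bdews)
spec <- transition_spec(onset_day = 35, ramp_days = 28, variance_gain = 4,
                        episode_type = "depressive")
sim <- simulate_patient(circadian_params(n_days = 56, seed = 5), spec)
analyze_patient(sim$activity, sim$symptoms)
#> <patient_report> sim-5: depressive episode, onset day 35
#>  indicator     z    tau  n         p sig direction
#>   variance 7.409 0.9947 28 1.275e-13  **  increase
#>   kurtosis 7.251 0.9735 28 4.148e-13  **  increase
#>     acf720 7.448 1.0000 28 9.462e-14  **  increase
```

All three indicators rise steeply over the 28 pre-onset days (tau near 1),
exactly the signature the ramp injects. Group-level pooling over the shipped
reference table of eight published per-patient results:

```r
combine_group(load_reference_trends())
#> <group_report> 8 patients, alpha = 0.05
#>   acf720     combined p = 5.873e-08 (chi2 = 65.57, df = 16)
#>   kurtosis   combined p = 7.538e-06 (chi2 = 53.00, df = 16)
#>   variance   combined p = 1.006e-05 (chi2 = 52.23, df = 16)
#>   >=1 significant: 7 | all significant: 2 | acf decrease: 4 | acf increase: 1
```

Each indicator is significant at the group level (all combined p < 0.001);
seven of the eight patients show at least one significant pre-onset EWS
trend, and four show a significant acf-720 *decrease* — direction is
reported separately because the autocorrelation indicator moves both ways.

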