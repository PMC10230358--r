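---
title: "Detecting clinical deterioration in neonatal cCHD vital-sign streams"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting clinical deterioration in neonatal cCHD vital-sign streams}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Neonates with critical congenital heart disease (cCHD) are monitored
continuously in the perioperative period, producing per-second streams of
heart rate (HR), respiratory rate (RR), peripheral oxygen saturation
(SpO2), bilateral cerebral regional oxygen saturation (rSO2, by
near-infrared spectroscopy), invasive mean arterial blood pressure (IBP)
and end-tidal CO2 (EtCO2). Interpreting these streams is hard precisely in
this population: an SpO2 of 75% can be entirely normal for a cyanotic
lesion and lethal for an acyanotic one, and each infant has a baseline of
its own. `vitalwatch` implements a transparent, rule-plus-learning
detector that classifies every second of such a stream as stable,
unstable or sensor dysfunction, and aggregates the per-second labels into
clinically countable episodes.

## Model architecture

The detector fuses three submodels, evaluated per second `t`:

1. **Sensor dysfunction** (rules). IBP or SpO2 changing by more than 25
   points between consecutive seconds, rSO2 at the ends of its scale
   (<= 15% or >= 95%, where readings reflect escaping sensor light rather
   than physiology), and raw RR below 5 breaths/min. HR is deliberately
   excluded — a true cardiac arrest is indistinguishable from an HR sensor
   error. Each detection run masks the minute before its first and after
   its last detection; masked seconds are never classified for stability.

2. **Population-level parameter combinations** (one-class SVM). Each
   complete 5-vector `(HR, RR-trend, SpO2, rSO2, IBP)` is z-scored against
   the moments of its saturation stratum and reduced to a Mahalanobis
   distance `d = sqrt(z' S^-1 z)`. Vectors above the 80th distance
   percentile are presumed unstable and discarded; the remainder are split
   80:20 and a one-class SVM with a square-exponential (RBF) kernel and a
   5% soft margin `nu` is fitted on the training part. At run time a vector
   is unstable when the SVM finds it nonresemblant of stable combinations
   or when it crosses a static clinical cutoff.

3. **Patient-specific baseline deviation** (streaming medians). The
   distance stream is inflated by 20% during mechanical ventilation
   (EtCO2 > 0), which iatrogenically damps variation. The trend
   `Z(t)` (300-second moving median preceding `t`) is compared with the
   patient's baseline `B(t)` (expanding median of all previous adjusted
   distances). `Z - B < 0` is movement toward the stratum centre —
   improvement; `Z - B >= 2 * SD` is instability, where `SD` is the
   standard deviation of the baseline-corrected distances after removal of
   their upper 20% (the supposedly unstable share), computed causally.

A second is unstable when no dysfunction is masked and either submodel 2
or 3 fires. The first hour of admission is warm-up: state accumulates, no
classification is emitted. A second is *episode*-unstable when at least 4
of the trailing 5 minutes (>= 240 of 300 seconds, nonconsecutive seconds
count) are raw-unstable; maximal constant-label runs become episodes,
counted with a 2-hour cap.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| jump threshold | 25 points | IBP/SpO2 artifact step between consecutive seconds (strict >) |
| rSO2 limits | 15 / 95 % | inclusive scale-rail artifact band |
| RR floor | 5 breaths/min | sensor malfunction below (strict <) |
| window pad | 60 s | dysfunction mask margin each side of a run |
| RR trend window | 300 s (>= 150 obs) | causal moving mean of raw RR |
| prefilter percentile | 80 | Mahalanobis cut before SVM training |
| `nu` | 0.05 | one-class SVM soft margin |
| `gamma` | `1/(5 * mean var of training z)` | RBF scale (heuristic; configurable) |
| ventilation multiplier | 1.2 | distance inflation while EtCO2 > 0 |
| `k` | 2 | instability threshold in trimmed-SD multiples |
| SD trim | 20 % | upper share removed before the noise SD |
| smoothing | >= 240 of 300 s | episode window rule |
| warm-up | 3600 s | first hour, no output |
| episode cap | 7200 s | maximum counted episode length |

Static cutoffs (HR outside 60–230 beats/min, smoothed RR above
90 breaths/min, IBP outside 20–90 mm Hg) are package defaults chosen for
clinical plausibility in neonates; the consensus values used at the
originating institution were never published. Every evaluation states the
cutoffs in its configuration snapshot, and they can be dropped entirely.

## Numerical and design choices

- **Time base.** Integer seconds on a contiguous 1 Hz grid; readers align,
  resolve duplicate timestamps last-wins, and fill gaps with all-missing
  seconds. No imputation anywhere.
- **Single-probe rSO2.** When only one cerebral probe reports, its value is
  used (maximizing data use); the scale-limit artifact rule is applied to
  each raw probe and to the fusion, since a railing probe is artifactual
  even if its partner is valid.
- **Missing EtCO2** means "not ventilated": the adjustment only inflates
  distances, so this is the conservative reading.
- **Stratification at exactly 90%** mean SpO2 goes to the high-saturation
  stratum, and uses all non-missing SpO2 seconds before any artifact
  masking.
- **Percentiles** use linear interpolation (`quantile` type 7); ties at the
  prefilter threshold are retained — discarding is the exception. The
  trimmed SD drops the largest `floor(0.2 n)` values, matching a
  sort-and-drop oracle exactly.
- **Causality.** `Z`, `B` and `SD` at time `t` use only values before `t`;
  `SD` is recomputed on a 60-second cadence and held in between, which
  keeps the stream computable in one pass. The streaming medians are
  implemented in C++ (two balanced multisets for the expanding median) and
  are tested for exact equality against full batch recomputation.
- **Covariance ridge** of `1e-6 * trace/5` is added only when the z-score
  covariance is not positive definite.
- **The 20% held-out partition** is used solely to log a sanity-check
  inlier rate; no threshold is ever tuned on it.
- **Unknown gaps** (missing-data seconds) up to 60 s flanked by the same
  label are bridged so a dropout does not split an episode; longer gaps
  break runs and stay unclassified. Smoothed labels mark the window-end
  second; run segmentation then recovers episode extent.
- **SVM training size** is capped at 10,000 vectors (seeded subsample of
  the 80% partition) to keep the quadratic-cost solver tractable on pooled
  cohorts.
- **Persistence** writes all model constants as full-precision text
  (`%.17g`), so a reloaded model reproduces the decision function
  bit-identically.

## What the simulator emulates — and what it does not

No public data exist for this population, so the package ships a
generator whose defaults are the study conditions:

- **Centres and dispersions** come from the published stratified cohort
  medians and IQRs (e.g. low-saturation stratum: HR 159, RR 34, SpO2 77,
  rSO2 55, IBP 51), with SD = IQR/1.349.
- **Variance partition.** Cohort IQRs mix between-patient differences with
  within-record variation. Each record draws a patient-specific baseline
  offset carrying 60% of the cohort variance (the range of published
  intraclass correlations for repeated vital signs in intensive care, and
  the premise of the baseline-deviation submodel), and wanders around it
  with the remaining 40%.
- **Two timescales plus jitter.** Within-record dynamics are a slow AR(1)
  (coefficient 0.999/s; drifts over tens of minutes) and a fast AR(1)
  (0.9/s; breathing, movement, behavioural state) in equal shares, plus
  small iid measurement jitter (HR 3, RR 2, SpO2 1, rSO2 1.5, IBP
  2 units). Real monitor traces are smooth at the 5-minute-median scale
  yet noisy second-to-second; a single-timescale process cannot be both.
- **Correlation** is mildly positive HR–RR (0.3) and SpO2–rSO2 (0.5),
  otherwise zero — a simulator choice; institutional correlation matrices were
  never published.
- **Training cohorts contain deterioration.** The fitted stratum model is
  meant to be trained on real admissions, which include unstable time;
  the 80th-percentile prefilter exists to strip that contaminated tail.
  `simulate_training_cohort()` therefore injects deterioration episodes
  (~17% of time) and ventilation periods into its 48 admissions. Training
  on curated stable-only data leaves a frontier that excludes roughly a
  fifth of the stable distribution by construction — a property worth
  knowing when fitting this class of model.
- **Clip ranges** keep clean records strictly inside the rSO2 (15, 95)
  artifact band, so artifact truth is exactly what was injected.

The simulator does not model beat-to-beat waveforms, pathology-specific
hemodynamics, medication effects, or circadian structure. Passing tests on
it demonstrate that the pipeline implements its rules exactly and detects
the kinds of sustained multi-parameter shifts it injects — not clinical
performance on real neonates, which requires retrospective expert review.

## Known limitations

- A patient whose baseline sits in the population tail of its stratum is
  flagged persistently by the population-level submodel even when stable —
  the alarm-fatigue risk inherent to normalized population models; the
  baseline submodel exists to counterbalance it. On simulated stationary
  records the post-warm-up unstable fraction is typically 0–5% but can
  exceed it for tail patients.
- The deviation rule is one-sided by design: movement toward the stratum
  centre is never unstable, although some true deteriorations (e.g.
  normalization of a compensatory tachycardia) can present that way.
- Episode scoring against synthetic truth uses interval overlap (any
  overlap = detected; under 50% coverage = partial), an evaluation-protocol
  simplification of expert adjudication.

## Problem sizes used in checks

The shipped tests fit stratum models on a 48-admission simulated cohort
(3 h each, pooled ~500k vectors, SVM subsampled to 10k), classify 3–6 h
records, and verify streaming statistics against batch oracles on 2 h
streams; `scripts/acceptance.R` fits on 5,000 vectors for the soft-margin
check and runs three 6 h detection scenarios. These sizes make every check
reproducible on a single CPU in minutes while keeping all window rules
(5-minute frames, 1-hour warm-up, 2-hour caps) at their native scale.
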