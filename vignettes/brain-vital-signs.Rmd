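---
title: "Brain vital signs from auditory ERPs: models, pipeline and statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Brain vital signs from auditory ERPs: models, pipeline and statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(brainvitals)
```

## The measurement framework

Three auditory event-related potentials (ERPs), each summarized by a peak
amplitude (µV) and latency (ms), form a six-dimensional "brain vital signs"
profile:

* **N100** — a negative deflection near 100 ms indexing auditory sensation,
  elicited by tones;
* **P300** — a positive deflection near 300 ms indexing attention/working
  memory, elicited by rare *deviant* tones embedded in a stream of frequent
  *standards* (the oddball paradigm, 80%/20% by default);
* **N400** — a negative deflection near 400 ms indexing semantic processing,
  elicited by the second word of spoken prime–target pairs when the target is
  semantically incongruent with its prime ("bread–window" vs
  "bread–butter"); half the pairs are congruent by default.

The package implements the full workflow around this profile: a forward
simulator with known ground truth, the extraction pipeline, 0–100
standardized scoring against a reference cohort, test–retest reliability,
and covariate-adjusted group comparison.

## The synthetic-data generator

`synthesizeRecording()` is a deliberately simple forward model: each ERP is a
Gaussian-windowed deflection with configurable amplitude, latency and width
(FWHM), placed on the scalp channels (Fz, Cz, Pz) with fixed per-component
weights, on top of additive noise. Defaults:

| component | polarity | FWHM | window (ms) | electrode |
|---|---|---|---|---|
| N100 | − | 50 ms | 70–150 | Cz |
| P300 | + | 80 ms | 160–450 | Pz |
| N400 | − | 100 ms | 280–610 | Cz |

Design notes:

* **Template widths.** Widths were chosen so that each template's spectrum
  sits essentially inside the pipeline's 0.5–20 Hz passband: the zero-phase
  band-pass then attenuates true peak amplitudes by at most ≈ 4% (N400) and
  ≈ 2% (N100/P300). A much narrower N100 (e.g. 30 ms FWHM) would place
  substantial energy above 20 Hz and make its true amplitude unrecoverable
  by construction, so the default is 50 ms.
* **Channel weights** are 1.0 on each component's measurement electrode so a
  noiseless recording round-trips exactly; the other channels carry smaller
  copies (frontal-dominant for N100, parietal for P300, centro-parietal for
  N400).
* **Deviant placement.** Deviant positions are pseudorandomized with no two
  deviants adjacent (uniformly over all such arrangements); runs of deviants
  would dilute the oddball effect. This constraint is configurable.
* **Stimulus timing** is configuration, not contract: defaults are 600 tones
  at 0.5 s ISI (120 deviants) followed by 60 word pairs (prime→target SOA
  0.9 s, pair period 2.2 s), i.e. roughly a six-minute stimulus sequence.
* **Noise** is a mixture of 1/f-shaped and white noise (default 10 µV total
  SD per scalp channel, 80% 1/f by variance — a realistic residual level for
  band-limited single-trial EEG), plus blink artifacts: ~400 ms biphasic
  waveforms on the EOG channel at a Poisson rate, propagated to the scalp
  with fixed frontal-dominant coefficients.
* **Word responses.** Primes and targets both receive a small auditory
  response; only incongruent targets additionally receive the N400 template.
  The incongruent-minus-congruent difference wave therefore isolates the
  N400 exactly, mirroring how the pipeline measures it.

What the generator does **not** emulate: realistic head-volume conduction,
inter-trial latency jitter, alpha rhythms, electrode drift or movement
artifacts. Passing recovery tests therefore demonstrate correctness of the
pipeline's arithmetic under the stated noise model, not device-grade
performance on human EEG.

### Cohort mode

`simulateCohort()` draws whole cohorts: Group A (n = 58 male adolescents,
age 16.24 ± 0.76, two sessions two days apart, 46 retested, 6 excluded for
data quality, 43 fluent English speakers) and Group B (n = 135, ages 8–83,
one session, one participant missing N100). Per-measure population means/SDs
default to the published normative descriptives of the two cohorts. Sessions
are bivariate normal with per-measure test–retest correlation ρ (defaults
0.45–0.70, strongest for latencies); the session-2 N400 amplitude is
multiplied by a habituation factor (default 0.815, the published ratio of
session means), emulating the well-known short-interval N400 habituation.
Age slopes default to small negative trends for P300 and N400 amplitude
only, the two measures with robust published age effects.

This missingness structure has a pleasing consequence: the session-1
complete-case set is 38 (Group A, fluent, included) + 134 (Group B with
N100) = 172 rows, so the multivariate error df is 164 — exactly the error df
of the published analysis.

"Table mode" emits the drawn measures directly so the statistics can be
tested at scale; "recordings mode" synthesizes full sessions for end-to-end
pipeline runs. The truth table always records every drawn value, including
values withheld from the measurement table by QC.

## The extraction pipeline

`processRecording()` chains, in order:

1. **Band-pass 0.5–20 Hz** — 4th-order Butterworth applied forward and
   backward (zero phase, so latencies are not shifted).
2. **Ocular correction** — a normalized least-mean-squares (NLMS) adaptive
   filter per scalp channel with EOG as reference (3 taps, step 0.001).
   The small step matters: larger steps let the weights chase instantaneous
   signal–reference correlations and measurably cancel stimulus-locked
   signal (~5% amplitude at step 0.01); at 0.001 the leakage is negligible
   while blink weights still converge within seconds.
3. **Segmentation** into [−100, +900] ms epochs around each analyzable
   marker, with per-channel baseline correction over [−100, 0] ms. Epochs
   overlapping a recording edge are dropped and counted.
4. **Wavelet smoothing** — symlet-4 periodic DWT per epoch and channel, soft
   universal threshold (noise scale from the finest-detail MAD) applied to
   the three finest detail scales only (≈ 31–250 Hz at 500 Hz). Coarser
   scales carry ERP morphology; thresholding them biases peak amplitudes
   systematically, which is why the shrinkage is restricted to scales above
   the ERP band. The transform is implemented in the package and verified by
   perfect-reconstruction and energy-preservation tests.
5. **Artifact rejection** — an epoch is flagged when any scalp sample
   exceeds ±75 µV; flagged epochs stay in the set for bookkeeping.
6. **QC** — a participant-session is excluded when the rejected fraction
   strictly exceeds 25% (strict inequality: exactly 25% is included).
7. **Averaging and peak measurement** — N100 and P300 are measured on the
   deviant-tone average (the standard-tone average is kept for plotting);
   the N400 on the incongruent-minus-congruent difference wave at Cz
   (configurable to incongruent-only). The peak is the most extreme interior
   local extremum of the appropriate polarity inside the component's
   window; ties break to the earliest sample; a window with no interior
   extremum falls back to the window-edge extremum and is flagged.
   Amplitudes are reported as magnitudes (µV), latencies at the peak sample
   (hence multiples of 2 ms at 500 Hz).

**Peak smoothing.** By default the peak *location* is found on a copy of the
average smoothed with a Gaussian kernel whose SD matches the component
template's SD (`peakSmooth = TRUE`); the amplitude is then read from the
*unsmoothed* average at that sample. Matched-kernel smoothing is the
maximum-likelihood latency estimator for a known template in Gaussian noise
and stabilizes the broad P300/N400 peaks dramatically, while reading the
amplitude off the raw average avoids the smoothing attenuation. The cost is
intentional: sub-kernel-scale double peaks are merged. With smoothing
disabled the detector is the plain most-extreme-local-extremum rule.

Under the default moderate-noise conditions (10 µV, 120 deviants, 60 word
pairs), pooled across components, the pipeline recovers latencies with a
median absolute error of one sample and amplitudes with a median relative
error under 10%; N400 amplitude is individually the noisiest measure (its
difference wave averages only ~30 trials per condition), consistent with the
low published test–retest reliability of that measure. A noiseless recording
is recovered exactly when the filtering stages are disabled; any band-pass
necessarily attenuates a finite-band template slightly, so bit-exactness
through the full filter chain is impossible by construction and the filter's
attenuation is bounded separately in the tests.

## Standardized 0–100 scoring

Against a reference distribution (per-measure mean µ and SD σ, built from an
included cohort with `buildReference()`), a measurement x maps to

* amplitude: `100 · clip((x − (µ − 3σ)) / 6σ, 0, 1)`
* latency: `100 · clip(((µ + 3σ) − x) / 6σ, 0, 1)`

so larger amplitudes and faster latencies score higher; µ scores 50; scores
clip at µ ± 3σ. The published scoring table's two middle-row formulas as
printed contradict its own boundary rows (at x = µ + 3σ the printed
amplitude formula yields 0 where the boundary row says 100); the package
implements the boundary-consistent orientation above and multiplies the
printed [0, 1] fractions by 100. `radarProfile()` applies this per measure;
`renderRadar()` draws the six-axis polygon with missing measures as gaps.

## Reliability statistics

All estimators are computed from mean squares, with established
implementations (base `aov`, Python `pingouin`) used as independent oracles
in the test suite, never as the implementation:

* **One-way ANOVA** between sessions: F = MS_between/MS_within on
  (1, 2n − 2) df. The label follows the conventional retest-table
  presentation; because the design is actually paired, this between-groups
  reading is conservative.
* **Cronbach's α** with k = 2 items: `2 (1 − (var₁ + var₂)/var_total)`.
* **ICC(A,1)** — two-way, single measures, absolute agreement:
  `(MS_R − MS_E) / (MS_R + MS_E + (2/n)(MS_C − MS_E))`, with the
  McGraw–Wong F-based confidence interval (Satterthwaite df) and the
  ICC = 0 test `F = MS_R/MS_E` on (n − 1, n − 1) df. The "two-way mixed"
  vs "two-way random" distinction affects interpretation, not this
  arithmetic. Absolute agreement penalizes constant shifts between
  sessions — a property the tests assert directly.

Incomplete pairs are dropped listwise, which reproduces the published pair
counts (46 for tone measures, 33 for the N400).

## Group comparison with age as covariate

`fitMancova()` fits the six-response multivariate linear model
`Y ~ age + group` on listwise-complete rows and computes, per term, the
hypothesis and error cross-product matrices, Wilks' Λ = det(E)/det(H + E),
Rao's F (exact for these single-df terms), and partial η² = 1 − Λ. Tests are
partial (Type III, the SPSS convention); hypothesis df is reported as
p·q = 6. Univariate follow-ups use `lm` + `drop1` partial F tests (equal to
Type III for this main-effects design). Estimated marginal means are group
predictions at the grand mean of age; the B − A difference equals the group
dummy coefficient, with t-based CI and no multiplicity adjustment by default
(a Holm option exists). `ageRegression()` fits per-group OLS on age and
reports decade-bin predictions with confidence intervals and R².

Case filtering is explicit: the multivariate filter is listwise across all
six measures (the achieved n and df are always reported), per-measure
filtering is available for purely univariate reporting.

## Numerical and design choices

* Detection windows, electrodes and wavelet parameters of the commercial
  device are unpublished; all defaults here are declared approximations
  chosen from the published normative ranges and standard ERP practice.
* Whether the device measures N100 from standards or deviants is not
  published; the package standardizes on the deviant average.
* Quantiles use linear interpolation (type 7); reference SDs use n − 1.
* Peak ties break to the earliest latency; degenerate variance structures
  (zero within-group variance, singular E) are reported as missing/errors
  rather than silently patched.
* Every figure's numeric content is also written as CSV; rerunning reporting
  on identical inputs reproduces those CSVs byte-for-byte.
* Simulation problem sizes in the test suite (e.g. 8 recordings for the
  recovery check, 1000 null replicates at n = 170 for calibration, 500
  replicates for EMM coverage) were chosen to bound Monte-Carlo error well
  below the asserted tolerances while keeping the suite fast.

## Limitations

* The deposited participant-level table of the original study is not
  distributed with the package, so its exact point statistics (e.g.
  α = 0.813 for N100 latency) cannot be re-derived here; the package instead
  verifies estimator correctness against independent implementations and
  reproduces the study's *structure* (cell counts, complete-case df,
  habituation direction) on matched simulations.
* The linear age model is a deliberate simplification; published evidence
  suggests non-linear lifespan trajectories.
* The simulator's noise model is stationary; real EEG quality varies within
  a session, which is one reason device measurements carry extra variance.
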