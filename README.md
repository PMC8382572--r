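# brainvitals

Simulation, extraction, scoring and reference statistics for auditory
event-related potential (ERP) **brain vital signs**: the N100, P300 and N400
peaks, each summarized by amplitude (µV) and latency (ms).

Rapid, automated ERP profiles are used as objective neurophysiological
markers in settings such as concussion management, where a short auditory
sequence (an oddball tone stream plus spoken word pairs) elicits responses
spanning sensation (N100), attention (P300) and semantic processing (N400).
Interpreting an individual profile requires normative reference
distributions, test–retest reliability of the measures, and group
comparisons that control for age. This package implements that entire
workflow for methods developers and biostatisticians:

* a **forward simulator** with known ground truth — stimulus sequences,
  multichannel recordings (Fz, Cz, Pz + EOG at 500 Hz), and whole two-cohort
  studies (an elite-athlete style retest cohort and a lifespan reference
  cohort) matched to published normative descriptives;
* the **extraction pipeline** — 0.5–20 Hz zero-phase band-pass, NLMS
  adaptive ocular correction against EOG, epoch segmentation with baseline
  correction, symlet-4 wavelet shrinkage, ±75 µV rejection with a
  strict >25% exclusion rule, and local-extremum peak measurement inside
  per-component windows;
* **standardized 0–100 scoring** against a reference cohort. For a
  measurement `x` with reference mean µ and SD σ:

  ```
  amplitude score = 100 · clip((x − (µ − 3σ)) / 6σ, 0, 1)
  latency   score = 100 · clip(((µ + 3σ) − x) / 6σ, 0, 1)
  ```

  so larger amplitudes and faster latencies score higher, µ scores 50, and
  scores saturate at µ ± 3σ;
* **reliability statistics** from mean squares — one-way ANOVA, Cronbach's
  α, and ICC(A,1) (two-way, single measures, absolute agreement) with
  McGraw–Wong confidence intervals;
* **group comparison** — six-response MANCOVA (Wilks' Λ = det(E)/det(H+E),
  Rao's F, partial η²) with age as covariate, Type III univariate
  follow-ups, covariate-adjusted estimated marginal means, and per-group age
  regressions with decade-binned predictions;
* **reporting** — descriptive tables, violin plots, six-axis radar profiles
  and waveform overlays, each with its numeric content also written as CSV.

## Worked example

```r
library(brainvitals)
sim <- simulateCohort(seed = 42)                      # two-cohort study, table mode

ref <- buildReference(sim$measurements[sim$measurements$group == "B", ])
print(refStats(ref), digits = 4)
#>          measure    mean     sd   n unit
#> 1 n100_amplitude  10.413  4.366 134   uV
#> 2   n100_latency 103.533 12.074 134   ms
#> 3 p300_amplitude  10.101  3.988 135   uV
#> 4   p300_latency 290.033 47.662 135   ms
#> 5 n400_amplitude   5.312  2.396 135   uV
#> 6   n400_latency 464.784 70.587 135   ms
```

The reference is the per-measure mean/SD of the simulated lifespan cohort
(n = 134 for N100 because one participant's N100 is missing, mirroring the
study design). Standardizing one retest-cohort participant against it:

```r
w <- measuresWide(sim$measurements, session = 1)
a1 <- w[w$group == "A" & complete.cases(w[, bvsMeasures()]), ][1, ]
radarProfile(setNames(as.numeric(a1[bvsMeasures()]), bvsMeasures()),
             ref, label = a1$participant_id)
#> StandardizedProfile A02
#> n100_amplitude   n100_latency p300_amplitude   p300_latency n400_amplitude
#>           69.2           24.3           25.4           60.3           32.0
#>   n400_latency
#>           61.0
```

Scores are 0–100 per axis: this participant has a large N100 (69) but a slow
one (24 — latency scores *decrease* with slower responses). Test–retest
reliability over the two sessions of the retest cohort:

```r
print(reliabilityTable(sim$measurements), digits = 3)
#>          measure  n anova_F anova_p cronbach_alpha   icc icc_ci_low icc_ci_high    icc_p
#> 1 n100_amplitude 46 0.78269 0.37868          0.752 0.597     0.3769       0.754 3.79e-06
#> 2   n100_latency 46 1.08939 0.29940          0.875 0.763     0.6017       0.863 6.53e-11
#> 3 p300_amplitude 46 0.00198 0.96462          0.859 0.756     0.5984       0.858 5.38e-10
#> 4   p300_latency 46 1.55041 0.21631          0.863 0.738     0.5558       0.850 3.17e-10
#> 5 n400_amplitude 33 8.01981 0.00618          0.420 0.218    -0.0748       0.496 6.40e-02
#> 6   n400_latency 33 1.97988 0.16424          0.750 0.572     0.2895       0.763 8.84e-05
```

Five measures show moderate-to-good reliability; N400 amplitude is the
outlier (significant session effect, low ICC) because the simulator applies
the known short-interval N400 habituation to session 2. The group comparison
with age as covariate:

```r
tab <- mancovaTable(w)
print(tab$multivariate, digits = 3)
#>        term wilks_lambda       F df_hypothesis df_error         p partial_eta_squared   n
#> 1 intercept       0.0309 858.657             6      164 4.32e-121              0.9691 172
#> 2       age       0.9295   2.073             6      164  5.90e-02              0.0705 172
#> 3     group       0.9665   0.946             6      164  4.64e-01              0.0335 172
```

Note the achieved complete-case set (172 rows → multivariate error df 164),
which the simulated missingness structure reproduces from the study design.
`tab$univariate` and `tab$emm` hold the per-measure follow-ups and the
covariate-adjusted B−A marginal mean differences.

A thin command-line wrapper over these functions ships in
`inst/scripts/brainvitals.R` (`simulate`, `process`, `score`, `reliability`,
`compare`, `report`, `run-all`), writing a JSON run manifest next to every
output.

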