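Package: brainvitals
Title: Brain Vital Signs from Auditory Event-Related Potentials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation, extraction, scoring and reference statistics for
    auditory event-related potential (ERP) "brain vital signs". Generates
    synthetic oddball-tone and word-pair EEG sessions with known ground truth;
    extracts N100, P300 and N400 amplitudes and latencies through a band-pass /
    ocular-correction / wavelet-denoising / epoch-rejection / peak-detection
    pipeline; standardizes measurements against a reference cohort onto a
    0-100 scale; and computes test-retest reliability (one-way ANOVA,
    Cronbach's alpha, intraclass correlation ICC(A,1) with confidence
    intervals) and group comparisons (MANCOVA with Wilks' lambda, univariate
    follow-ups, covariate-adjusted estimated marginal means, and age
    regressions) from first principles.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    signal,
    ggplot2,
    jsonlite,
    rlang,
    yaml
Suggests:
    testthat (>= 3.0.0),
    car,
    emmeans,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
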