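Package: biostress
Title: Objective Stress Measurement from Autonomic Biosignals During Endoscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An event-anchored analysis pipeline for objective stress
    measurement from multi-channel autonomic biosignals recorded during
    colonoscopy: facial electromyography (corrugator supercilii and
    zygomaticus major), electrocardiography, skin conductance level and
    peripheral skin temperature. Provides per-modality signal conditioning
    (zero-phase Butterworth filtering, Hilbert-envelope demodulation,
    moving-average smoothing, detrending), Hamilton-Tompkins QRS detection,
    one-minute analysis windows anchored at examination start, cecal
    intubation and examination end with automated artifact screening,
    window-mean feature extraction, and one-sided Mann-Whitney group
    comparisons with chi-square, Fisher and t tests for cohort tables.
    A synthetic-session generator with ground-truth envelopes and beat
    times makes every stage testable without patient recordings and
    supports Monte-Carlo null-calibration and power analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    broom,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
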