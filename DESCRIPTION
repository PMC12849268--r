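Package: fatigueflow
Title: Time-on-Task EEG Fatigue Markers, P50 Sensory Gating, and
    Adaptive Go/No-Go Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for studying cognitive state fatigue
    ("fatigability") with electrophysiological, behavioral, and subjective
    markers. Implements EEG preprocessing (zero-phase band-pass and notch
    filtering, average re-referencing, Gratton-Coles ocular correction,
    peak-to-peak artifact rejection, spectral and event-related epoching),
    tapered-FFT band-power extraction of frontal theta and occipital alpha
    over task blocks, p50 paired-click sensory-gating suppression ratios with
    degenerate-case rules, time-on-task slope statistics with winsorization,
    linear mixed-model group inference with Type-III ANOVA and
    Benjamini-Hochberg corrected post hoc contrasts, and a simulator/scorer
    for a gamified adaptive Go/No-Go task with signal-detection metrics. A
    synthetic cohort generator with analytic ground truth (fixed-frequency
    band carriers in pink noise, stereotyped p50 templates, bounded
    visual-analogue-scale drift) makes every stage testable without access
    to clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    signal,
    lme4,
    lmerTest,
    emmeans,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
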