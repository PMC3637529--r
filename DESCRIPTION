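Package: dailycyto
Title: Simulation and Within-Person Analysis of Daily Cytokine Monitoring Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for studying daily immune-monitoring designs in which a small
    cohort is followed over consecutive days with serum multiplex cytokine panels
    and twice-daily visual-analogue fatigue reports. Provides a seeded synthetic
    cohort generator with planted adipokine-fatigue coupling and a
    leptin-correlated cytokine block; subject-centered z-score standardization
    and 3-day moving-average smoothing; per-subject and pooled correlation
    tracking of analytes against fatigue; Benjamini-Hochberg FDR-thresholded
    correlation networks with force-directed layout; and an extreme-day
    classification experiment (linear support vector machine, stratified
    cross-validation, cross-cohort transfer). A pipeline orchestrator reproduces
    the full analysis end-to-end with a run manifest.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    rlang,
    tidyr,
    igraph,
    e1071,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
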