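Package: pfk
Title: Biomechanics of Freezing of Gait, Step Initiation and Reactive Posture
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Signal-processing and statistics pipeline for instrumented
    assessment of postural control in movement disorders. Quantifies
    freezing of gait from lumbar vertical acceleration with a windowed
    spectral freeze index, extracts anticipatory postural adjustment (APA)
    onset, duration and normalized peak amplitude from step-initiation
    trials, computes center-of-pressure and center-of-mass anteroposterior
    displacement metrics for support-surface perturbation trials using a
    segmental anthropometric model, and aggregates trial-level metrics into
    subject-by-condition percent-change outcome statistics with one-sample
    t tests. Ships seedable synthetic-trial generators with known ground
    truth for every paradigm so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    signal,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
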