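Package: rspi
Title: Regional Strain Pattern Index and Dyssynchrony Analysis for CRT Response
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Scores left-ventricular mechanical dyssynchrony from segmental
    longitudinal strain curves using the Regional Strain Pattern Index (RSPI),
    a 0-12 point sum of four dyssynchrony components assessed in the three
    apical echocardiographic views. Also provides the classical/heterogeneous
    strain-pattern classifier, classical time-to-peak dyssynchrony indexes
    (Yu index, interventricular mechanical delay, septal-to-posterior wall
    motion delay, diastolic filling fraction), the volumetric responder
    definition for cardiac resynchronization therapy, and a cohort-level
    evaluation pipeline (2x2 diagnostics, ROC with optimal cutoff, univariate
    logistic regression, nonparametric group tests). A seeded synthetic
    waveform and cohort generator makes the whole pipeline testable without
    patient data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
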