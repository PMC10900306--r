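Package: airpaths
Title: Treatment Trajectories of Newly Diagnosed Asthma and COPD Patients
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds new-user cohorts of adults newly diagnosed with asthma or
    COPD from OMOP-shaped observational tables, collapses prescription or
    dispensing records into drug eras, resolves cross-class overlaps into
    mono- and combination-therapy treatment events, classifies first
    treatment transitions against guideline-derived intensity ladders
    (step-up, step-down, switching, exacerbation markers), and aggregates
    per-patient trajectories into sunburst-style prefix trees. Includes a
    synthetic-data generator that plants known trajectories and transition
    types so every pipeline stage can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    readr,
    tibble,
    rlang,
    stats,
    tools,
    utils,
    yaml,
    jsonlite,
    withr
Suggests:
    arrow,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
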