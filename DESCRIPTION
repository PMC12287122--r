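Package: picsmorph
Title: Levator Ani Morphometry in the 3D Pelvic Inclination Correction System
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Landmark-based morphometry of the levator ani muscle (LAM)
    subdivisions in a patient-specific pelvic coordinate frame (the 3D
    Pelvic Inclination Correction System, PICS). Builds the PICS frame from
    bony landmarks (inferior pubic point, sacrococcygeal articulation,
    bilateral ischial spines), rigidly transforms annotated 3D points
    between scanner and PICS space, computes muscle lengths and signed
    plane angles per subdivision, aggregates group summaries and
    between-group differences, and estimates two-rater intraclass
    correlation with confidence intervals and Landis-Koch labels. Includes
    a seeded synthetic-cohort generator emulating control and prolapse-case
    groups so the whole pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    readr,
    purrr,
    rlang,
    jsonlite,
    yaml,
    parallel,
    stats,
    utils,
    tools,
    lattice,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
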