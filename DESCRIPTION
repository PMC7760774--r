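Package: critspeed
Title: Critical Speed Field Testing and VO2max Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Analysis pipeline for running-based critical speed (CS) field
    testing. Extracts CS and the finite above-CS distance capacity (D') from
    3-minute all-out test speed traces, processes graded exercise tests with
    supramaximal verification bouts into VO2max, gas exchange threshold and
    50%-delta speeds, applies pacing and verification quality-control screens,
    fits and applies a CS + sex prediction equation for relative VO2max, and
    computes reliability statistics (typical error, CV%, ICC). Includes a
    seeded synthetic-cohort generator so every stage of the pipeline can be
    exercised and validated without laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
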