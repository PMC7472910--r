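Package: tactdd
Title: Tactile Direction Discrimination Testing and Node-Level
    Lesion-Symptom Mapping
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.com")
Description: Quantitative tools for tactile direction discrimination (TDD)
    testing after stroke: simulation and scoring of the adaptive staircase
    protocol (transformed up-down with an area-under-curve score),
    derivation of normative impairment thresholds (flat per age band or
    age-linear), relative TDD scores and abnormality classification,
    Crawford-style single-case deficit tests, exact Fisher association of
    lesion location with impairment including a conditional exact odds-ratio
    bound, and node-level lesion-symptom mapping on parcellation volumes.
    Includes generators for psychometric observers, normative cohorts with a
    linear age effect, and phantom parcellations with injected node-linked
    deficits, plus a packaged patient cohort table.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    RNifti,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
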