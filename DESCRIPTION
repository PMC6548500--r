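Package: ichnometry
Title: Ichnometric Inference from Human Footprint Measurements
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for the quantitative study of fossil human footprints
    (ichnometrics): validated measurement tables of anatomical footprint
    landmarks, derived shape indices (foot index, arch angle), log-shape
    principal component analysis with iterative imputation of missing
    measurements, hierarchical morphotype grouping and minimum-number-of-
    individuals estimation, and per-individual biometric inference of
    stature, body mass, age class and sex from allometric calibrations.
    Includes the published measurement tables from the Upper Palaeolithic
    trackway record of the Basura cave (Toirano, Italy) as fixtures, and a
    seeded synthetic trackway generator for parameter-recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
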