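Package: ferrotrace
Title: Stable-Isotope Tracer Analysis of Iron Absorption Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulation and analysis machinery for multi-tracer stable-isotope
    iron-absorption cross-over trials. Generates synthetic cohorts and
    forward-simulates erythrocyte iron isotope patterns, inverts measured
    patterns into per-tracer incorporated iron and fractional iron absorption
    by isotopic dilution, and computes the trial summary statistics (geometric
    means with confidence intervals, relative bioavailability, paired
    log-scale tests with Bonferroni adjustment, and paired sample-size
    calculations). Companion tools cover iron speciation arithmetic (ferrous
    fraction, EELS white-line L3/L2 ratios with a configurable valence
    calibration), CIELAB colour differences, and R-Index multiple-difference
    sensory testing with permutation critical values.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), jsonlite, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
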