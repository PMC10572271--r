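Package: peachspec
Title: Hyperspectral Defect Classification with CARS-Based Wavelength Selection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Chemometric pipeline for classifying fruit defects from
    near-infrared reflectance spectra (900-1700 nm). Provides black/white
    reflectance calibration, the standard spectral pretreatments (SNV,
    baseline, median smoothing, Savitzky-Golay and gap-segment derivatives),
    a PLS1 engine, wavelength selection by competitive adaptive reweighted
    sampling (CARS) with mean-impact-value (MIV), successive-projections
    (SPA) and uninformative-variable-elimination (UVE) second stages,
    genetic-algorithm-tuned and least-squares support-vector classifiers,
    Kennard-Stone set partitioning, macro-averaged discriminant-rate
    evaluation, and a seeded synthetic four-class spectra generator for
    end-to-end testing.
License: MIT
Encoding: UTF-8
Imports:
    e1071,
    jsonlite,
    signal,
    stats,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
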