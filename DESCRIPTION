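Package: scampr
Title: Mass-Activity Profile Correlation Scoring for Bioassay-Guided
    Fractionation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Ranks candidate bioactive compounds in a chromatographically
    fractionated extract by correlating each mass bin's intensity profile
    across sequential fractions with the fractions' bioactivity profile
    (SCAMP: Scaling of Correlations between Activity and Mass Profiles).
    Provides peak-list preprocessing for ultra-high-resolution mass spectra
    (blank averaging and subtraction, signal-to-noise filtering,
    carbon-13 de-isotoping, ppm-width mass binning), three correlation-based
    scoring methods including chromatographic grouping, enrichment-curve
    evaluation of ranked candidate lists, molecular-formula mass arithmetic
    for deprotonated ions, and a synthetic fractionation simulator with
    known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllGenerics.R'
    'AllClasses.R'
    'chem-mass.R'
    'enrichment.R'
    'fraction-io.R'
    'pipeline.R'
    'preprocess.R'
    'scampr-package.R'
    'scoring.R'
    'synthetic.R'
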