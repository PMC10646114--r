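Package: ameloSex
Title: Enamel Peptide Sex Estimation and Osteological Cohort Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Sex estimation of human skeletal remains from sex-chromosome
    specific amelogenin peptides in tooth enamel, analysed by liquid
    chromatography-mass spectrometry. Computes theoretical monoisotopic m/z
    for a panel of AMELX/AMELY/ENAM marker peptides, extracts ion
    chromatograms from centroided MS1 mzML data within a ppm mass window,
    detects and integrates elution peaks, and turns per-marker evidence into
    categorical sex calls (male, female, probable female, undetermined) with
    extraction-blank quality control. Companion osteological analyses cover
    canine buccolingual-diameter sex classification with observer-error
    statistics (technical error of measurement, reliability) and Cohen's
    kappa agreement against the peptide calls, wear-corrected age-of-onset
    estimation for linear enamel hypoplasia, and cohort sex-ratio profiling
    with demographic extremeness bands. A synthetic-data generator produces
    chromatographic runs and osteological tables with known ground truth for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    mzR,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    e1071,
    withr,
    xml2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
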