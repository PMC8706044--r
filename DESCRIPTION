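Package: polarscreen
Title: Hidden-Target Screening for Polarity-Extended LC-MS Metabolomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An untargeted metabolomics annotation workflow for serial
    RPLC-HILIC (polarity-extended) LC-MS data. Provides feature-table
    quality control against spiked internal standards, triplicate consensus
    alignment, blank subtraction, retention-time partitioning into HILIC and
    RPLC regimes, retention-time-index calibration of LogD(pH 7) from a
    reference-standard mixture, composite candidate scoring against a
    compound database with successive elimination filters (LogD sign,
    chemotaxonomy), reference-standard confirmation into a five-level
    identification scheme, and OPLS-DA with S-plot based selection of
    features common to two mass-spectrometer systems. A synthetic-data
    module generates feature tables, compound databases and MS/MS spectra
    with known ground truth so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    mixOmics
Config/testthat/edition: 3
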