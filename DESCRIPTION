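Package: hextomo
Title: Desk-Scale Subtomogram Averaging for Hexagonal Membrane Arrays
Version: 0.1.0
Authors@R:
    person("Array", "Tools", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates cryo-electron tomograms of curved-membrane hexagonal
    arrays of chemosensory core signalling units (CSUs) and implements the
    matching subtomogram-averaging pipeline at desk scale: membrane-surface
    particle seeding, missing-wedge-compensated constrained cross-correlation
    alignment, geometric curation of particle lattices, wedge-weighted Fourier
    averaging, gold-standard Fourier shell correlation with local-resolution
    estimation and filtering, C2 symmetrisation, and Hill fitting of FRET
    kinase dose-response data. Volumes are exchanged as MRC2014 maps and
    particle tables as tab-separated text.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
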