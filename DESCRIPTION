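Package: msdeconv
Title: Deconvolution of LC-ESI-MS Metabolomics Spectra with 13C-Labeling
    Support
Version: 0.1.0
Authors@R:
    person("msdeconv", "developers", email = "msdeconv@example.org",
           role = c("aut", "cre"))
Description: Groups adducts, in-source fragments, isotopologues and
    U-13C-labeled counterparts of coeluting analytes in LC-ESI-MS peak
    tables into pseudo spectra. Associates 12C monoisotopic peaks with
    their fully 13C-labeled partners to fix carbon counts, annotates
    large uncommon neutral losses via constrained sum-formula triplets,
    performs filtered accurate-mass decomposition (Golden-Rules style
    heuristics plus an oxygen/phosphorus rule), computes mass isotopomer
    ratios with biomass normalization, group fold-changes and
    Benjamini-Hochberg adjusted t-tests, and matches pseudo spectra
    against reference lists by dot-product similarity. Includes a
    synthetic-data generator with full ground truth for validation, a
    minimal mzML MS1 reader for extracted ion chromatograms, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
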