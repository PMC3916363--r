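Package: glycoquant
Title: Quantitative Glycomics of Amide-15N Metabolically Labeled N-Glycans
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Relative quantification of N-glycans from dual metabolic
    stable-isotope labeling (amide-14N/15N-Gln) MALDI-TOF experiments.
    Computes glycan composition masses and theoretical m/z libraries,
    aggregated isotopic envelopes with partial 15N enrichment at aminosugar
    amide nitrogens, centroids and normalizes profile spectra, assigns
    compositions to observed peaks, deconvolves overlapping light/heavy
    isotope clusters by two-template non-negative least squares, aggregates
    replicate ratios into mean and CV%, and emits up/no/down change calls
    with glycan-class annotation (including bisecting GlcNAc). Includes a
    synthetic-data generator reproducing the replicate structure of a
    dual-labeled secretome comparison for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    pracma,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    mzR,
    withr
Config/testthat/edition: 3
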