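Package: crcconcord
Title: Mutational Concordance Analysis for Paired Primary and Metastatic Tumors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for somatic mutational concordance between
    patient-matched primary and metastatic tumor sequencing, as used in
    deep targeted-panel and whole-genome studies of colorectal cancer.
    Implements allele-frequency call filtering for panel and tumor/normal
    trio regimes, comparative rescue genotyping of private calls,
    shared/private classification with multi-region resolution,
    GC loess-normalized tumor/normal depth-ratio copy number with
    gene-level deletion and gain calls, microsatellite instability typing
    from marker panels, and clinical association tests, together with a
    synthetic trio-cohort generator with recorded ground truth so every
    stage is testable without access to controlled patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    yaml,
    optparse
Config/testthat/edition: 3
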