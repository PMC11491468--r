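Package: cnaquiet
Title: Classification of Copy-Number-Quiet Tumors from Low-Coverage
    Whole-Genome and MLPA Copy-Number Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Implements a purity- and ploidy-aware pipeline for classifying
    tumors as copy-number-alteration (CNA) quiet or CNA-other. Provides
    stromal-contamination-corrected recalculation of the fraction genome
    altered (FGA) from segment tables, grid-based purity/ploidy fitting with
    consensus combination against an external estimate, panel-of-normals
    segment calling for low-coverage whole-genome sequencing bins, MLPA
    probe-ratio scoring for pre-screening, somatic-variant filtering with
    variant-copy linkage and binomial power QC, the cohort statistics used
    to characterize the resulting subclasses, and seeded synthetic-data
    generators that emulate every input so the whole pipeline is testable
    without access to controlled patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
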