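Package: vusplice
Title: Junction-Level Splicing Outlier Analysis and Functional Follow-Up for
    Splice-Site Variants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for resolving splice-site variants of uncertain significance
    from transcriptome and functional assay data. Computes junction-level
    percent-spliced (PS) values from STAR splice-junction tables, calls
    splicing outliers against a background cohort using Tukey fences,
    quantifies isoform fractions from TPM and classifies isoform structure
    (exon skipping, cryptic splice sites) against a canonical transcript with
    HGVS-style protein consequences, quantifies splicing-reporter
    percent-spliced-in (PSI) from fragment-analysis peak tables with one-way
    ANOVA and Monte-Carlo Dunnett post-hoc statistics, analyzes
    dihydroceramide/ceramide lipid ratios, and designs tiled antisense
    oligonucleotide walks. A seeded synthetic-data generator emulates every
    input so the whole pipeline is testable without restricted patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    jsonlite,
    IRanges,
    GenomicRanges,
    S4Vectors,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
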