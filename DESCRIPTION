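Package: sacscreen
Title: Statistics for SAC-Inhibitor Resistance Screens and Cell-Line Panel Association
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Analysis toolkit for pooled CRISPR knockout screens of spindle assembly
    checkpoint (SAC) inhibitor resistance and for downstream cell-line panel analytics.
    Implements key-sequence sgRNA extraction and barcode demultiplexing of raw screen
    reads, median-of-ratios normalization, paired differential guide enrichment,
    alpha-robust-rank-aggregation (alpha-RRA) gene scoring with permutation p-values,
    preranked and single-sample gene-set enrichment scores, expression- and
    aneuploidy-quartile drug-sensitivity association with linear covariate
    partialization, a genome-wide gene-drug ranking-percentile profile, a 0-5 mitotic
    aberration severity scoring scheme with rank-based group comparison, and seeded
    synthetic-data generators with ground-truth ledgers for every input the pipeline
    consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    limma,
    Biostrings,
    fgsea,
    withr
Suggests:
    testthat (>= 3.0.0),
    DESeq2
Config/testthat/edition: 3
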