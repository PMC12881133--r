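Package: sustainseq
Title: Sustained Transcriptional Response Classification for Stimulation
    Time-Course RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for two-timepoint stimulation RNA-seq
    experiments (e.g. microglia under pro-inflammatory LPS and
    anti-inflammatory IL-4 stimulation). Provides a negative-binomial
    count simulator with planted transcriptional programs, a documented
    simplified negative-binomial Wald differential-expression engine
    (median-of-ratios normalization, Cox-Reid adjusted gene-wise
    dispersions, per-contrast Benjamini-Hochberg adjustment), selection
    of sustained differentially expressed genes, four-way responder-set
    classification (stimulus-specific, common, opposite, ambiguous),
    hypergeometric over-representation analysis against GMT gene sets,
    and cross-dataset concordance reports (overlap, directionality
    quadrants, Spearman correlation of fold changes, top-K term
    overlap).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    DESeq2,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
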