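Package: mirex
Title: Predicting mRNA Expression from Promoter Sequence, Half-Life
    Features and miRNA Target Repression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A convolutional regression pipeline that predicts per-gene
    mRNA expression levels from a TSS-centered DNA window, eight mRNA
    half-life covariates, and a per-gene vector of expression levels of
    the miRNAs that target the gene. Implements residual-based selection
    of informative miRNAs by Spearman correlation between baseline-model
    residuals and TargetScan Cumulative Weighted Context++ Scores (CWCS),
    and a four-variant model comparison (baseline, all-miRNA, signed
    selection, absolute selection) with best-run aggregation, confidence
    intervals and significance tests. Includes a synthetic-data generator
    with planted motif, half-life and miRNA repression effects so the
    whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    methods,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
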