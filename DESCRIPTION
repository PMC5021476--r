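Package: mirlink
Title: Discovery of miRNA-mRNA Regulations by Inverse-Correlation
    Screening and Seed-Match Target Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrative pipeline for discovering candidate miRNA-mRNA
    regulations from paired expression cohorts. Implements prevalence
    filtering, quantile normalization, log2 transformation and per-batch
    mean centering of miRNA-isoform and gene expression matrices;
    median-based fold-change differential expression with Welch t-tests
    and Benjamini-Hochberg correction; a memory-bounded all-pairs
    Spearman inverse-correlation screen within histotype groups;
    simplified seed-match (TargetScan-style), duplex-alignment
    (miRanda-style) and seed-weighted ranking (TargetRank-style) target
    predictors; and the staged candidate funnel that joins correlation
    and prediction evidence into final regulation calls. A synthetic-data
    generator implants known negative monotone miRNA-gene couplings
    backed by genuine seed sites, so every stage of the pipeline is
    verifiable against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    stringr,
    ggplot2,
    generics,
    withr,
    yaml,
    jsonlite,
    stats,
    utils,
    limma,
    cluster
Suggests:
    testthat (>= 3.0.0),
    Biostrings,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors,
    optparse
Config/testthat/edition: 3
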