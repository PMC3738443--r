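Package: methylewas
Title: Genome-Wide DNA Methylation Case/Control Analysis for 450K Arrays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for epigenome-wide association studies on
    Illumina Methylation450-style beta-value matrices: detection-p masking and
    missingness filtering, empirical-Bayes batch adjustment on random CpG
    subsets, Infinium I/II chemistry harmonization by a quadratic mapping,
    covariate-adjusted per-CpG linear association with permutation p-values
    and Benjamini-Hochberg FDR, signal characterization (QQ data,
    hyper/hypomethylation directionality, biphasic p-value bands,
    intermediate-methylation enrichment), CpG-to-gene mapping with gene-set
    enrichment by Fisher's exact test, cross-cohort replication statistics,
    and an exact compositional/intrinsic decomposition of bulk methylation
    differences under a cell-subtype mixture model. Ships a seeded synthetic
    450K-like data generator so every stage is testable without external
    downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    stats,
    utils,
    yaml,
    jsonlite,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    sva,
    withr
Config/testthat/edition: 3
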