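Package: mastqtl
Title: Meta-QTL Analysis for Multiple Abiotic Stress Tolerance in Wheat
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for meta-QTL analysis of multiple abiotic stress tolerance
    (MAST) in bread wheat: merging published linkage maps into a consensus map,
    projecting per-study QTLs onto it, clustering projected peaks per chromosome
    with a Gaussian mixture model under five information-criterion votes
    (AIC, AICc, AIC3, BIC, AWE), forming and naming meta-QTLs (MQTLs),
    anchoring them on the physical genome, co-localising them with GWAS
    marker-trait associations and known stress genes, mining candidate genes
    with fold-change expression filters, scanning promoters for cis-regulatory
    elements, and detecting ortho-MQTLs shared with rice and maize. A synthetic
    data generator with known ground truth supports end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    BiocGenerics,
    Biostrings,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
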