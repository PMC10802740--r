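Package: csefinder
Title: Discovery of Cancer-Specific Exons from Exon-Level RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for discovering cancer-specific exons (CSEs) as
    candidate immunotherapy targets from exon-level RNA-seq expression.
    Implements exon read counting with union/nonunique semantics and
    read-length-aware FPKM normalization, tumor-versus-normal rank-sum
    statistics combined across tumor-type by normal-tissue pairs with a
    percentile-rank-weighted Stouffer composite Z-score, specificity
    filtering against the surfaceome and matrisome, curation checks
    (cross-resource validation, proteomics verification, normal-brain
    expression, 3'-coverage bias), Tier 1/2 assignment (paired-normal
    tissues, bone-marrow logistic model, bimodal nPSM cutoff), alternative
    splicing versus gene-level target classification, quartile binned
    tumor/normal scoring, and portal-ready exports. Ships a synthetic-data
    generator that plants known gene-level and alternatively spliced
    targets so every stage can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    stringr,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    mclust,
    digest,
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomicAlignments,
    Rsamtools
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
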