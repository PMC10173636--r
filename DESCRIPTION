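Package: lncscope
Title: Hybrid Annotation and Characterization of Long Non-Coding RNA Genes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for identifying long non-coding RNA
    (lncRNA) genes from three transcript-model sources (genome annotation,
    short-read assembly, long-read full-length sequencing) and characterizing
    them. Implements the identification cascade (length, exon-count,
    coding-overlap and coding-potential filters; chi-squared strand inference
    for unstranded long reads; intron-chain based three-source merging with
    contribution accounting; an expression gate), a five-way positional
    taxonomy relative to coding genes (antisense, intronic, divergent,
    convergent, intergenic), conservation-track scoring with matched random
    background, stage and tissue expression analytics (tau specificity,
    expressed calls, stage sharing, correlation structure, PCA, tissue
    specificity), co-expression based cis and trans target calling with module
    detection, and a negative-binomial Wald test for mutant-versus-wild-type
    contrasts. A synthetic-data module generates every input with planted
    ground truth so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    generics,
    stringr,
    ggplot2,
    jsonlite,
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    DESeq2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
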