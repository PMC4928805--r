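Package: promstates
Title: Promoter Chromatin-State Classification and Transition Analysis from ChIP-seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A promoter-centric pipeline for histone-modification ChIP-seq in
    two-condition designs (e.g. a drug-sensitive versus a resistant tumour
    line). Promoters are extracted around transcription start sites and
    classified by CpG content (HCP/ICP/LCP) with a sliding-window test on GC
    fraction and CpG observed/expected ratio; aligned tags are smoothed with a
    fixed-width Gaussian kernel and peaks are called greedily under a
    nucleosomal exclusion zone; per-promoter occupancy of H3K4me3, H3K9ac and
    H3K27me3 (raw tag counts or fitted-peak sums) drives a four-state
    chromatin classification (active, repressive, bivalent, none); state
    transitions between conditions are tabulated and related to gene
    expression (FPKM) via Spearman correlation, group comparisons and
    fold-change tables. A synthetic-data module generates genomes, tag
    libraries and expression with planted ground truth so every stage is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    GenomicRanges,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
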