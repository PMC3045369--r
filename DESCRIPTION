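Package: tilecall
Title: Ratio-Based Detection of Differential mRNA Processing from Tiling
    Microarrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects differentially processed genes (DPGs) and
    differentially expressed genes (DEGs) from two-condition genomic
    tiling microarray experiments. Probe-affinity variation is cancelled
    by forming within-block control/treatment intensity ratios; a
    hierarchical cascade of one-sample t-tests, a per-transcript one-way
    ANOVA and a whole-transcript t-test then classifies each annotated
    transcript isoform. The false discovery rate is estimated empirically
    from balanced combinations of forward and reversed ratios built with a
    geometric-mean pseudo-replicate, and detected DPGs are tentatively
    labelled as alternative polyadenylation, splicing or transcription
    initiation events from the spatial pattern of deviating exons. A
    seeded simulator of tiling-array experiments with known ground truth
    supports benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    limma,
    readr,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
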