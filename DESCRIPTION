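Package: peakscape
Title: Replicate-Consensus ChIP-Seq Peaks, TSS Annotation, Signal
    Profiles and Expression Stratification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Author: Package Author [aut, cre]
Maintainer: Package Author <maintainer@example.org>
Description: Downstream analysis of transcription-factor ChIP-seq
    experiments with unequal-quality replicates. Consumes MACS2
    narrowPeak calls, tagAlign/BED alignments, GENCODE-style GTF gene
    models and ENCODE blacklists, and provides blacklist filtering with
    an asymmetric-threshold replicate-consensus rule, nearest-TSS peak
    annotation into seven genomic categories, depth-normalized signal
    tracks and TSS metaprofiles, multi-set merged-peak Venn counts, and
    FPKM-based expression stratification of promoter-bound versus
    unbound genes. A seeded synthetic-data generator emulates the full
    study design (planted promoter binding shared between two factors,
    replicate-specific noise peaks, duplicate reads, negative-binomial
    count tables) so every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    jsonlite,
    methods,
    purrr,
    rlang,
    rtracklayer,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    ggplot2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
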