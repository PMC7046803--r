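Package: mirreg
Title: Regulatory Region Occupancy and Expression Analysis for Circulating microRNAs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for mapping the transcription-factor regulatory landscape of
    microRNA loci from ChIP-seq peak tracks. Builds strand-aware proximal
    promoter and enhancer windows around miRNA genes (including host-gene
    windows for intronic miRNAs), counts transcription-factor binding sites per
    window with cross-cell-line peak merging, classifies windows by histone
    marks (H3K4me3, H3K4me1, H3K27ac), scans bound regions for binding motifs
    with position weight matrices, and aggregates occupancy by TF family and
    disease subtype. A companion qPCR stage implements hemolysis quality
    control, multi-reference comparative-CT quantification, fold changes and
    group comparisons for circulating miRNA panels. A synthetic-data generator
    produces complete desk-scale fixtures with planted ground truth so every
    stage is testable without external downloads.
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
    S4Vectors,
    purrr,
    readr,
    rlang,
    stringr,
    tibble,
    tidyr,
    withr,
    yaml,
    Biostrings,
    rtracklayer,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
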