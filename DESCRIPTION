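Package: sineac
Title: Activity-Dependent Histone Acetylation at SINEs, B-Box Motifs and
    Transcription-Factory Colocalization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidy reimplementation of the computational pipeline used to
    link neuronal-activity-dependent H3K9K14 acetylation at short
    interspersed elements (SINEs) with TFIIIC binding and gene relocation
    to transcription factories. Provides a binomial sliding-window
    differential ChIP-seq caller with signed -log10(p) change tracks and a
    discreteness-aware false discovery rate estimate; genomic-context
    classification, repeat-family enrichment against random backgrounds,
    strand-oriented TSS tag-density metaprofiles and acetylated-SINE
    density profiles with Mann-Whitney testing; B-box position-weight
    matrix scanning and region-set over-representation tests; a 3D
    immuno-DNA FISH analysis (nucleus masking, intensity-weighted object
    centroids, mean+1SD RNA polymerase II positive-voxel calling,
    anisotropic nearest-positive-voxel distances and 225-nm colocalization
    calls); and seeded synthetic-data generators with ground truth for
    every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.2)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    jsonlite,
    withr,
    igraph,
    tiff,
    stats,
    tools,
    utils,
    methods,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    Biostrings,
    EBImage,
    rtracklayer
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
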