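Package: somvn
Title: Chromatin State Assignment from Accessibility Signal Shapes
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Learns representative chromatin accessibility signal shapes from
    binned genome-wide DNase-seq or ATAC-seq coverage using a self-organizing
    map with signal-dependent variable neighborhood sizes (SOM-VN), collapses
    shift-equivalent shapes by normalized cross-correlation, associates the
    learned shapes with regulatory-element chromatin states (promoter,
    enhancer, weak) by overlap with ChromHMM-style annotations, and assigns
    states to unseen chromosomes with overlapping-window containment matching
    consolidated by dynamic programming. Includes permutation null models,
    region-level precision/recall and PR-AUC evaluation, and a synthetic
    genome generator for fully reproducible benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    methods,
    yaml,
    jsonlite,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
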