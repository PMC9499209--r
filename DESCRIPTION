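Package: footprintCNN
Title: Transcription Factor Binding Site Classification from ATAC-seq
    Cleavage and Footprint Profiles
Version: 0.1.0
Authors@R:
    person("Maintainer", "Package", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Classifies motif-predicted transcription factor binding sites
    (MPBSs) as bound or unbound from paired-end ATAC-seq data. Converts
    fragments into per-base Tn5 cut-count tracks channelized by read strand
    and fragment size, computes normalized cleavage signal, slope and
    single-base footprint-score tracks, assembles 9x1000 per-site input
    tensors, and trains a small multi-kernel one-dimensional convolutional
    network to predict binding probability. Includes PWM scanning with
    p-value derived score thresholds, ChIP-seq summit based labeling,
    balanced dataset construction, AUROC evaluation against footprint-score
    and footprint-overlap baselines with Friedman-Nemenyi rank comparison,
    a fragment-level ATAC-seq simulator with plantable footprints, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    optparse,
    stats,
    tools,
    utils,
    IRanges,
    Biostrings,
    Rsamtools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
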