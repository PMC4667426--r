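Package: tfpairs
Title: Discovery of Collaborating Transcription-Factor Pairs from
    Binding-Site Co-Occurrence in Promoter Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Identifies potentially collaborating transcription-factor
    (TF) pairs from the joint distribution of their predicted binding
    sites (TFBSs) across a set of promoter sequences.  A TFBS-sequence
    frequency matrix is filtered for over-represented and sparse motif
    columns, per-sequence important TFBS types are selected by positive
    pointwise mutual information (PMI), same-type overlapping sites are
    resolved towards the transcription start site, distance-constrained
    TFBS pairs are enumerated with homotypic-cluster de-duplication, and
    each pair receives a weighted cumulative PMI score corrected by the
    average product correction (APC) and transformed to a z-score.
    Includes readers for FASTA promoters, TRANSFAC-style count matrices
    and tab-separated hit tables, a log-odds stand-in motif scanner, a
    spike-in simulator that plants a coupled motif pair into synthetic
    promoter background with ground truth, and network/edge-list output
    for the significant-pair collaboration graph.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    igraph,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
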