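Package: methylmotif
Title: Bacterial Methylome Determination from Single-Molecule Sequencing Kinetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Determines bacterial methylomes from per-position polymerase
    kinetics summaries of single-molecule real-time (SMRT) sequencing.
    Modified bases (m6A, m4C) are called by a Phred-scaled t-test kinetic
    score against an in-silico sequence-context reference; methyltransferase
    recognition motifs, including degenerate IUPAC and bipartite Type I
    sites, are discovered from the top-scoring hits by enrichment-seeded
    search with greedy IUPAC generalization; a score threshold is then set by
    the unassigned-hit-fraction rule and per-motif extent of methylation,
    complementary-strand motif pairing and restriction-modification system
    type calls are reported. A seeded synthetic-kinetics generator emulating
    the methylome complements of six well-characterized bacteria makes every
    stage testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    S4Vectors,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
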