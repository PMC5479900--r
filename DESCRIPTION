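Package: gsiScreen
Title: Candidate-Gene Screening for S-RNase-Based Gametophytic
    Self-Incompatibility
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Screens proteomes and transcriptomes for candidate determinants
    of S-RNase-based gametophytic self-incompatibility (GSI). Implements
    RNase-T2 family classification by conserved-site amino-acid patterns,
    isoelectric-point computation by bisection over an explicit pKa table,
    C-terminal motif analytics for SKP1/SSK1 proteins (WAFE variants, GVDED
    tails, type I/II calling), FPKM normalisation and tissue-specificity
    calling, and reference-based clade placement by pairwise global
    alignment, Poisson-corrected distances and neighbor joining. A decision
    engine combines the four S-RNase screening criteria (homology, pattern-4
    absence, basic pI, style-restricted expression) and the SSK1 rules into
    per-gene verdicts. A seeded synthetic-data generator with planted
    positives and a ground-truth table makes every stage verifiable at desk
    scale.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors,
    ape,
    phangorn,
    yaml,
    jsonlite,
    Rcpp,
    stats,
    utils,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
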