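Package: oabseq
Title: Mapping Oxidized and Abasic Sites in RNA from Aniline-Cleavage Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Nucleotide-resolution mapping of RNA oxidative damage from
    aniline-cleavage sequencing libraries (AlkAnilineSeq and its
    Mg2+-fragmentation variant OAbSeq). Counts 5'-read extremities from
    SAM/BAM alignments with a -1 backshift onto the cleaved nucleotide,
    computes per-position scores (stop ratio, NCleavage, NormGcounts with a
    sliding-window median background, and a Poisson-style random error),
    calls oxidation sites with a three-criterion filter, compares protocols
    and conditions, and ranks the most damaged sites. A chemistry-aware read
    simulator with truth tables makes the whole pipeline testable without
    external data, and a self-contained module implements LC-MS external
    calibration (relative response factors, three normalization schemes) and
    the DPD/KIO3 free-chlorine calculation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    tibble,
    dplyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    withr,
    methods,
    stats,
    yaml,
    Biostrings,
    Rsamtools,
    GenomicAlignments,
    GenomicRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
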