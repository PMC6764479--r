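Package: tdgf
Title: Discovery and Validation of Transcription-Derived Gene Fusions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects composite (fused) genes from sequence similarity
    networks by non-transitive triplet decomposition and clique-separator
    verification, localizes fusion breakpoints by pairwise alignment
    against parent genes, quantifies junction-spanning reads from RNA-seq
    and ribosome-footprint data with tiered expression calls and a
    tissue-enrichment statistic, tests enrichment of fusion loci in
    segmental-duplication regions with a permutation null backed by an
    exact hypergeometric tail, and maps fusion origins onto a species
    tree. Includes a synthetic-data generator that plants fusions,
    junction reads and segmental-duplication placements with known ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    igraph,
    ape,
    yaml,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
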