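Package: afescan
Title: Palindromic Operator Models and Regulon Prediction for
    LuxR-Family Quorum-Sensing Regulators
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Predicts binding sites for LuxR-family quorum-sensing
    transcription factors in bacterial genomes from the modular palindromic
    structure of their operators. Builds position-wise probabilistic profiles
    from combinatorially enumerated palindrome variants, scans both strands of
    a genome for non-overlapping high-scoring hits, merges hits into predicted
    binding sites (PBSs), classifies PBSs by genomic context (sense intergenic
    regions and start-codon proximity), gates candidates by sigma-70 promoter
    proximity, refines candidates with ZOOPS expectation-maximisation motif
    discovery and an exact-p-value PSSM rescan of intergenic regions, and
    reports a candidate regulon table. Includes a synthetic bacterial
    chromosome simulator with planted motif instances for end-to-end
    benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
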