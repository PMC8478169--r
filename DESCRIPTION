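Package: copperscan
Title: Copper-Resistance Gene Repertoire Profiling with Profile HMMs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested re-implementation of a copper-resistance comparative-genomics
    pipeline for marine bacteria. Provides a self-contained profile hidden Markov
    model engine (HMMER3 ASCII input/output, profile construction from alignments,
    local Viterbi scoring in log2-odds, Gumbel E-values), catalog-driven resistome
    tabulation with smallest-E-value duplicate-hit resolution and E-value
    sensitivity sweeps, BLAST-style homolog retention filtering (similarity and
    length-ratio bounds), detection of the five-gene merR-copA core cluster on
    annotated replicons with genomic-island overlap annotation, and qPCR
    delta-delta-CT relative expression analysis with reference-gene stability
    screening and normality-gated significance testing. A synthetic-data module
    generates proteomes, annotated replicons, and CT tables with known ground
    truth so every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    Rcpp,
    withr,
    stats,
    utils,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
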