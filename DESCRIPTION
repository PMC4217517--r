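Package: replisim
Title: Stochastic Simulation of DNA Replication Timing in Metazoan Cells
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates the DNA replication program of an asynchronous
    population of virtual cells on a binned chromosome. A fixed pool of
    replication forks initiates bidirectional replication at sites drawn
    from an Initiation Probability Landscape (IPLS), advances at constant
    velocity, and is recycled on collision or at chromosome boundaries.
    Simulated measurement devices produce replication-timing profiles,
    flow-sorted (Repli-seq style) fractions, single-molecule (DNA combing)
    eye/hole/eye-to-eye statistics, nascent-strand initiation profiles and
    global initiation rates. Utilities convert bedgraph signal (for
    example DNase hypersensitivity) into landscapes, and an independent
    plain-R reference simulator provides cross-validation oracles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    GenomicRanges,
    IRanges,
    Rcpp,
    S4Vectors,
    methods,
    optparse,
    rtracklayer,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
SystemRequirements: C++17
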