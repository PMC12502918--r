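Package: kmerscreen
Title: Syncmer-Based Metagenomic Read Classification with a
    Run-Length-Compressed k-mer Index
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds a compressed reference index for metagenomic read
    classification. Reference assemblies are reduced to canonical open
    syncmers, arranged as a k-mer-by-assembly bit matrix whose columns are
    reordered with a greedy nearest-neighbour heuristic to minimise
    run-length-encoding cost, and stored row-wise with an adaptive
    run-length encoding. Reads (or read prefixes, emulating nanopore
    adaptive sampling) are classified by an exact binomial significance
    test on syncmer match counts per assembly. Includes seeded synthetic
    mock-community and read simulators, confusion-matrix evaluation with
    genus-level label rollup, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
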