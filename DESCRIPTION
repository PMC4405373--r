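Package: mitescope
Title: Structural Discovery and Characterization of Miniature
    Inverted-Repeat Transposable Elements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: De novo identification of miniature inverted-repeat
    transposable elements (MITEs) in small AT-rich genomes by terminal
    inverted repeat (TIR) and target site duplication (TSD) structure,
    followed by family clustering, consensus building, genome-wide
    remnant mining, superfamily classification, Kimura two-parameter
    divergence and amplification-burst analysis, neighbor-joining trees,
    gene-association statistics against a Monte-Carlo placement null,
    MITE insertion polymorphism candidate selection via reciprocal best
    hits and synteny, and small-RNA positional profiling.  Includes a
    synthetic-genome simulator that plants element families with known
    coordinates and divergence structure so every stage of the pipeline
    can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    IRanges,
    Rcpp,
    ape,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
SystemRequirements: NCBI BLAST+ (blastn, makeblastdb) for the
    clustering prefilter and remnant mining.
Config/testthat/edition: 3
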