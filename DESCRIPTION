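Package: porecode
Title: Constrained Coding for Nanopore DNA Data Storage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Design and evaluation of delta-thresholded constrained de Bruijn
    codes for DNA data storage read through nanopore sequencers. Builds k-mer
    transition graphs pruned by current-level differences and homopolymer
    run-length, computes their capacity, constructs finite-state encoders via
    the state-splitting algorithm, simulates the nanopore read channel (dwell
    repetition, band-limiting low-pass filter, Gaussian noise), mitigates
    intersymbol interference, basecalls signals with an exact Viterbi decoder
    over a k-mer hidden Markov model, and wraps everything in an end-to-end
    storage pipeline with a Reed-Solomon outer code over GF(2^12) and
    multi-read consensus. Includes Levenshtein error profiling with
    insertion/deletion/substitution breakdown and batch sweep drivers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    igraph,
    jsonlite,
    stats,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
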