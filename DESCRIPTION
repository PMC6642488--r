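Package: dgrfinder
Title: Detection of Diversity-Generating Retroelements in Genomes and
    Metagenome Assemblies
Version: 0.1.0
Authors@R:
    person("DGR", "Finder Developers", email = "dgrfinder@example.org",
           role = c("aut", "cre"))
Description: Identifies diversity-generating retroelements (DGRs) in
    bacterial genome and metagenome assemblies without relying on
    alignment against a reference DGR collection. Template repeats (TR)
    and reverse transcriptase genes (RT) are located with
    position-weight-matrix motif states embedded in a generalized
    (explicit-duration) hidden Markov model decoded by Viterbi; variable
    repeats (VR) are recovered from each candidate TR with an
    adenine-aware local aligner seeded by adenine-wildcard k-mers, so
    that heavily mutated repeats with short identical segments are still
    found. Elements are assembled into intact or partial DGR cassettes,
    cassette patterns are classified by element order and orientation,
    redundancy is removed by greedy identity clustering of RTs, the
    substitution spectrum of TR-VR pairs is summarized, partial elements
    can be confirmed from raw sequencing reads, and a synthetic genome
    generator provides ground-truth fixtures for end-to-end evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    IRanges,
    jsonlite,
    Rcpp,
    S4Vectors,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    rtracklayer,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
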