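Package: lncortho
Title: Comparative Feature Analysis of Syntenic Long Non-Coding RNA Loci
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative genomics of syntenic long non-coding RNA
    gene pairs such as NEAT1 and MALAT1. Implements synteny-anchored gene
    delineation from promoter and 3'-end structure anchors, a seed-and-extend
    local nucleotide aligner, average nucleotide identity (ANI) from
    identity-weighted local-alignment hits, archetype (maximally dissimilar
    representative) selection, polyadenylation-signal calling with windowed
    single-motif rules, transposable-element annotation under the 80-80-80
    rule with presence/absence and excision calling across a phylogeny,
    detection of self-complementary (inverted-repeat) region pairs,
    G-quadruplex and hexamer profiling, nucleotide-usage profiles, base-pair
    covariation from multiple sequence alignments, position-weight-matrix
    promoter scanning with exact dynamic-programming p-values, and a
    synthetic-locus generator that evolves two-gene loci with planted ground
    truth along a user-supplied tree for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    ape,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
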