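Package: amplicall
Title: Anchored Alignment and Indel Calling for CRISPR Amplicon Sequencing
Version: 0.1.0
Authors@R: person("amplicall", "developers", role = c("aut", "cre"),
    email = "amplicall@example.org")
Description: Quantifies CRISPR editing outcomes from paired-end amplicon
    deep-sequencing reads. Reads are quality-trimmed and filtered, anchored
    to the amplicon reference by exact terminal k-mer lookup in a suffix
    array, and aligned by affine-gap dynamic programming between the
    maximally distanced anchors. Insertion and deletion events are
    left-aligned, reconciled between mates, and summarized within the
    sgRNA+PAM window as wild-type, frameshift, or non-frameshift read
    pairs. A pairwise chi-square test of proportions compares
    non-frameshift read fractions between sample groups. A paired-end read
    simulator with a known allele spectrum supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    optparse,
    Rcpp,
    S4Vectors,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
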