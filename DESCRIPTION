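Package: sulfsig
Title: Signature-Motif Screening for Bacterial Delta-4,5-Hexuronate-2-O-Sulfatases
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for identifying bacterial Delta-4,5-hexuronate-2-O-sulfatases
    (sulfatase family S1_9) from protein sequence alone: homolog screening by
    pairwise percent identity, redundancy removal, conservation profiling of
    aligned families, extraction and scanning of anchored signature motifs
    (including the five PB2SF-anchored motifs of the family), neighbor-joining
    phylogeny with bootstrap support and outgroup-rooted clade-membership
    tests, ORF-level sequence properties (GC content, translation, molecular
    weight, isoelectric point), and a synthetic protein-family simulator with
    planted motifs for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    ape,
    seqinr,
    Rcpp,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
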