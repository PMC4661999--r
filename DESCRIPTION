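Package: omfinish
Title: Optical-Map-Guided Genome Assembly Finishing and Evaluation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for finishing draft genome assemblies against optical
    (whole-genome restriction) maps. Digests assembled sequences in silico,
    places contigs onto chromosome-scale restriction maps by dynamic-programming
    fitting alignment under a relative sizing-error model with permutation-based
    placement significance, builds chromosome-level consensus sequences with a
    two-tier primary/secondary assembly strategy (gap filling and replacement of
    ambiguous sequence from a secondary assembly), and evaluates assemblies with
    standard contiguity metrics and feature-response curves computed from
    anomalously mapped read pairs. Includes a simulator of truth genomes,
    mis-assembled derived assemblies, noisy optical maps and read-pair
    alignments with truth tables, so that every stage can be exercised offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    Rsamtools,
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
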