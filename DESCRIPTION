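Package: amplitag
Title: Multitag 454 Amplicon Pipeline for Insect Endosymbiont Community
    Profiling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for multitag 454 (GS FLX Titanium) 16S rDNA amplicon
    studies of insect endosymbiont communities. Simulates tag-encoded
    pyrosequencing reads with homopolymer-dominated error profiles and a
    known ground-truth community, demultiplexes reads by exact key and
    multiplex identifier (MID) matching, assembles per-tag consensus
    sequences with a window-match seed-extension algorithm, clusters
    consensus sequences into operational taxonomic units (OTUs) with
    per-sample read counts and percentages, and classifies or places OTU
    sequences against a reference set (nearest reference, neighbour
    joining, Fitch parsimony insertion). A one-command pipeline driver
    with a manifest of checksummed intermediates ties the stages together.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    Rcpp,
    ape,
    yaml,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
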