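Package: gcrsim
Title: Simulation and Analysis of CRISPR-Induced Global Chromosome Rearrangement
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to simulate and analyse global chromosome rearrangement
    (GCR) induced by CRISPR-Cas9 cleavage of dispersed repeat elements
    (LINE-1-like and Alu-like). Provides a synthetic genome generator with
    embedded repeat copies carrying exact and mismatched guide target sites,
    a double-strand-break/NHEJ-style cut-and-rejoin rearrangement simulator
    with full junction and copy-number ground truth, exhaustive guide
    multi-target enumeration with up to two mismatches, binned read-depth
    copy-number-variation differencing against a control sample, interval
    permutation (shuffle) enrichment tests, a Monte-Carlo null for intra-
    versus inter-chromosomal translocation counts, breakpoint-to-nearest-
    repeat distance profiles, and a repeat-anchored long-read split-mapping
    translocation caller with precision/recall evaluation against simulated
    truth. Standard interchange formats (FASTA, BED, BEDPE, PAF, TSV) are
    read and written throughout.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
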