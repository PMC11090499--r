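Package: hetseq
Title: Event-Pair Analysis of Ossification-Sequence Heterochrony
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for comparative analysis of developmental (ossification)
    sequences on a fixed phylogeny: event-pair encoding of event-onset
    timelines, detection of heterochronic shifts between taxa and along tree
    branches, rank-based principal component ordination of onset sequences,
    unordered-parsimony ancestral-state reconstruction (Fitch length, MPR
    sets, ACCTRAN/DELTRAN resolutions) with clade-synapomorphy extraction,
    readers and writers for NEXUS and TNT character matrices and delimited
    event tables, and a synthetic-data generator (Yule trees, Mk characters,
    timelines with branch-localized heterochronic transpositions) with full
    per-branch ground truth for validating every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    optparse
Config/testthat/edition: 3
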