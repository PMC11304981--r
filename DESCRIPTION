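Package: ncvaars
Title: Interpretation of Giant-Virus Aminoacyl-tRNA Synthetase Gene Trees
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to interpret maximum-likelihood gene trees of
    aminoacyl-tRNA synthetases (aaRSs) encoded by large and giant DNA
    viruses (Nucleocytoviricota). Reads Newick trees carrying dual
    SH-aLRT/ultrafast-bootstrap node labels, roots them on the branch
    separating the major bacterial and archaeal clades, extracts
    supported viral clades, and assigns each clade one of six
    horizontal-gene-transfer scenarios relative to the eukaryotic
    radiation (proto-eukaryotic, ancient, recent, virus-to-eukaryote,
    unresolved, or prokaryotic). Also computes transfer bootstrap
    expectation (TBE) support from bootstrap tree sets, enumerates the
    fifteen constrained topologies consumed by approximately-unbiased
    tests, performs ANI-based genome dereplication, alignment gap
    trimming, aaRS assignment from homology-search hit tables, and
    tree-based contamination filtering, and detects virus-to-virus
    transfers, displacements and losses inside viral clades. A
    synthetic-data generator plants known evolutionary events in
    annotated gene trees so every stage is testable without external
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    igraph,
    jsonlite,
    tibble,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    Biostrings
Config/testthat/edition: 3
RoxygenNote: 7.3.3
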