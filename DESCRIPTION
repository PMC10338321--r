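Package: covet
Title: Phylogeny-Aware Covariation Analysis of Protein Residue Pairs
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Ranks residue pairs of a protein family by their tolerance to
    nonconcerted variation across an evolutionary tree (the CovET method),
    alongside the mutual-information comparator ET-MIp. Builds Evolutionary
    Trace sequence distances and UPGMA trees from multiple sequence
    alignments, scores every pair of query-mapped columns over all tree
    partitions, and evaluates the resulting rankings against protein
    structures (CASP-style contact prediction, selection cluster weighting
    z-scores, ligand-proximity functional sites, hypergeometric overlap) and
    against deep mutational scanning epistasis models. Includes seeded
    simulators for tree-structured alignments with planted coupled positions
    and toy structures with planted spatial clusters.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    bio3d,
    igraph,
    ape,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
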