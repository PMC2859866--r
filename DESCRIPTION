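Package: mitorearr
Title: Rearrangement Phylogenies of Plant Mitochondrial Genomes with
    Tandem Duplication Resolution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs the structural evolution of plant mitochondrial
    master circles from gene-order rearrangements. Builds signed Genome
    Structure Sequences (GSS) from annotated genomes via reciprocal-best-hit
    marker families and co-linear backbone fragments, resolves duplicated
    synteny anchors under a tandem-duplication-with-partial-loss (TDPL)
    model using a neighborhood graph, computes exact Hannenhalli-Pevzner
    inversion distances and parsimonious sorting scenarios, infers
    distance (BIONJ) and parsimony-style (MGR-like) phylogenies with block
    jackknife support and ancestral gene orders, places duplication and
    loss events on branches, and cross-checks structure trees against
    Kimura two-parameter sequence-divergence trees. A seeded simulator of
    circular signed-block genomes evolving by inversions, tandem
    duplications with partial loss and anchor losses makes every stage
    testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    ape,
    Biostrings,
    igraph,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
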