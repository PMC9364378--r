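Package: phylocore
Title: Core-Genome Phylogenomics of Bacterial Clades
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative phylogenomics of bacterial genome
    collections built from per-genome annotation tables: definition of a
    single-copy core-gene panel by occupancy and normalized-size filters,
    percentage-nucleotide-similarity (PNS) species delimitation on the
    concatenated core alignment, gene-content dissimilarity (Hellinger +
    Bray-Curtis), pan/core rarefaction with one-genome-per-species
    resampling, core-genome synteny (adjacency links, synteny index,
    reference-guided reordering of draft-genome scaffolds, consensus
    architecture networks), and Robinson-Foulds topology concordance
    testing against a bootstrap null. A synthetic clade generator with
    known ground truth makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    ape,
    vegan,
    igraph
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
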