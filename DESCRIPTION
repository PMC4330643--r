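Package: capclade
Title: Census, Annotation and Phylogenetic Partitioning of the Alveolate
    eIF4E Cap-Binding Protein Family
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for surveying the eukaryotic translation initiation
    factor 4E (eIF4E) family in dinoflagellates and related alveolate and
    heterokont lineages. Implements an iterative, query-expanding protein
    family census built on exact local alignment with Karlin-Altschul
    E-values, reference-anchored alignment to the murine eIF4E core with
    murine residue numbering, diagnostic cap-binding and eIF4G-motif
    annotation, neighbor-joining phylogenies with nonparametric column
    bootstrap, fixed-topology LG+Gamma pruning likelihoods, taxon-aware
    clade and sub-clade partitioning with species-representation tables,
    composition-bias chi-squared tests, sequence-logo information content,
    and a synthetic family simulator with known clade truth for offline
    validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    phangorn,
    phytools,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
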