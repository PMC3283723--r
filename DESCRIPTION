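Package: mitophylo
Title: Mitochondrial DNA Phylogeography: Haplogroup Classification,
    Parsimony Trees, Rho Dating and Population Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for phylogeographic analysis of human mitochondrial DNA
    in the reference (rCRS-like) coordinate frame: parsing and calling of
    reference-relative variants with the standard phylogenetic exclusion
    mask and functional (synonymy) classification; haplogroup assignment
    against cumulative motifs of a haplogroup tree with frequency and
    component-share tables; most-parsimonious haplotype tree construction
    with an exhaustive small-instance oracle and an annotated newick
    dialect; rho-statistic coalescence dating with Saillard errors under
    three calibrated mutation clocks; haplotype diversity and neutrality
    statistics (haplotype diversity, segregating sites, mean pairwise
    differences, Ewens theta-k with exact confidence bounds, Tajima's D,
    Fu's Fs, Fisher's exact test); pairwise FST with nonmetric MDS and PCA
    ordination; and seeded synthetic-data generators (star clades of known
    age, Kingman coalescent samples under constant size or sudden
    expansion, haplogroup mixtures) so the whole pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    vegan
Suggests:
    testthat (>= 3.0.0),
    ape,
    phangorn,
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
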