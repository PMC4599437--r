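Package: bgclineage
Title: Assembly-Line Analysis and Evolutionary History of Modular NRPS/PKS
    Gene Clusters
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to analyse modular non-ribosomal peptide synthetase (NRPS)
    and type-I polyketide synthase (PKS) biosynthetic gene clusters from
    domain-organization annotations: a parser for the compact domain-string
    notation, segmentation of multi-gene assembly lines into modules,
    prediction of peptide/polyketide backbone chemistry by the assembly-line
    rule, cross-strain ortholog grouping with presence/absence matrices,
    neighbor-joining phylogenetics with bootstrap support, and Dollo-parsimony
    reconstruction of cluster gain and loss on a species tree. Ships the
    complete cluster inventory of the five Herbidospora type strains as a
    worked data set, plus seeded simulators with known ground truth for every
    pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
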