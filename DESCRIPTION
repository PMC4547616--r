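Package: lipidgen
Title: Combinatorial Generation and Hierarchical Classification of
    Glycerolipid Structures for Lipidomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Enumerates chemically feasible glycerolipid and
    glycerophospholipid structures from curated chain and class building
    blocks, annotates them with shorthand nomenclature, systematic names,
    molecular formulas, monoisotopic and average masses and adduct m/z
    values, and organizes them into the seven-level analytical hierarchy
    (category, class, subclass, species, molecular subspecies, structural
    subspecies, isomeric subspecies) used to map mass-spectrometry
    outputs to candidate structures.  Includes m/z search with ppm or Da
    tolerance, identifier mapping between compound sets, and an
    evidence-linked annotation store for lipid occurrence and
    enzyme-reaction links.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    ChemmineOB,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
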