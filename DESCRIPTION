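Package: motubar
Title: DNA-Barcode MOTU Delimitation and Morphological Congruence
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A workflow for species delimitation from aligned CO1 DNA
    barcodes: Kimura two-parameter divergences, Neighbor-Joining trees
    with nonparametric bootstrap, tree-guided threshold clustering into
    molecular operational taxonomic units (MOTUs), congruence scoring
    against morphologically defined species, identity-based species
    naming against a local reference library, average-linkage clustering
    of standardized morphometric characters, and a calibrated sequence
    simulator that generates barcode datasets with known cluster
    structure for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    phangorn,
    seqinr,
    Matrix,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
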