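Package: pdbassemblies
Title: Identification, Naming and Analysis of Unique Macromolecular
    Assemblies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Standardises the annotation of macromolecular assemblies in
    archives of experimentally determined structures. Components of each
    biological assembly are mapped to reference accessions (UniProt for
    proteins, Rfam for RNA), combined with stoichiometry into canonical
    composition labels, and hashed so that every unique composition
    receives a persistent complex identifier. The package detects
    sub-assembly and super-assembly relationships, matches compositions to
    Complex Portal definitions, assigns human-readable names through a
    rule-based decision tree (Complex Portal, UniProt, Gene Ontology
    cellular-component terms, ribosome detection, antibody and entity
    names, curated overrides), and reports point-group symmetry
    consistency across instances of the same composition. A synthetic
    archive generator with machine-readable ground truth makes the whole
    pipeline testable without network access.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    digest,
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stringr,
    tibble,
    tidyr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
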