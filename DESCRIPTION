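Package: rxnscout
Title: Rule-Based Reaction Classification, Naming, and Condition
    Suggestion via Bond-Electron Matrices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analyzes chemical reactions given only their Reaction SMILES.
    Atom-mapped reactions are represented by Dugundji-Ugi bond-electron
    matrices; the product-minus-reactant transformation matrix identifies
    the reaction center and drives a rule cascade that classifies each
    reaction into one of ten medicinal-chemistry classes. Reactions are
    additionally named against a curated SMIRKS motif library, decomposed
    into functional groups, ring systems, formed rings and Bemis-Murcko
    scaffolds, and fingerprinted (MACCS or ECFP4) for Tanimoto similarity
    search over annotated reaction databases, from which solvent, catalyst
    and reagent suggestions are tallied by literature frequency. Chemistry
    primitives are delegated to the RDKit toolkit through a bundled
    batched worker.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
SystemRequirements: Python (>= 3.8) with the RDKit package available on
    the PATH as 'python' (configurable via option 'rxnscout.python' or
    environment variable RXNSCOUT_PYTHON).
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
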