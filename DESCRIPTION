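Package: homointer
Title: Interchain Contact Prediction and Complex Reconstruction for Homo-Oligomers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives predicted interchain residue-residue contacts for
    homodimers and homomultimers from a monomeric contact-map prediction by
    windowed subtraction ("relax removal") of true intrachain contacts
    computed from the monomer tertiary structure, evaluates the predictions
    with relaxed Top-k precision against true interchain contacts, and
    reconstructs the complex from the predicted contacts by
    contact-restrained rigid-body simulated annealing. Includes PDB
    preparation utilities (chain splitting, reindexing, chain
    homogenization), CASP RR contact-format input/output, a seeded random
    prediction baseline, and a synthetic homomultimer generator so the full
    pipeline is testable without external structure downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    bio3d,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'infer.R'
    'evaluate.R'
    'baseline.R'
    'constructors.R'
    'geometry.R'
    'contacts.R'
    'io.R'
    'prep.R'
    'reconstruct.R'
    'synthetic.R'
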