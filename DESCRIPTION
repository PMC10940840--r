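Package: pairzyme
Title: Enzyme Promiscuity Prediction from Substrate-Product Pairs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Screens candidate enzymes for their ability to catalyze a given
    substrate-product transformation. Mines substrate-product pairs from
    atom-mapped reaction SMILES using an atom-provenance rule, builds
    substrate-product-enzyme triads with EC-mismatch unlabeled examples,
    trains a positional-encoding-free transformer encoder-decoder under a
    positive-unlabeled regime with balanced undersampling, label-smoothed
    cross-entropy and dynamic purging of confidently-positive unlabeled
    examples, and ranks enzyme libraries by predicted catalysis likelihood.
    Includes a seeded synthetic-data generator with a planted, learnable
    motif signal so the full pipeline can be exercised without any external
    database.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ChemmineOB,
    data.table,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    pROC
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
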