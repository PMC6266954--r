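Package: mirtype
Title: Tissue-Specific Typing of Validated miRNA-Target Interactions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Characterises validated miRNA-target interactions in a tissue
    cohort by testing the association between miRNA, gene and protein
    expression profiles with a permutation global test (score test for
    group association), and classifies each pair as mRNA degradation,
    translation inhibition, no interaction, or no interaction* (protein
    data unavailable). Includes cross-assay sample matching for
    TCGA-barcode-style identifiers, multi-tissue comparison views, a
    synthetic-cohort generator with planted interaction types for
    desk-scale validation, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
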