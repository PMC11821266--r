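Package: sfbias
Title: Interrogating Dataset Bias in Protein-Ligand Binding Affinity Scoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A toolkit for decomposing the apparent accuracy of
    protein-ligand binding-affinity scoring functions into dataset bias
    versus learned structure. Provides bias-only baseline predictors
    (ligand-identity, pocket-composition, their ensemble and
    concatenation), bias-resistant benchmark splits (identical-ligand
    clusters with controlled pK spread, peptide holdout, time splits),
    structural stress tests (progressive steric-clash translations and
    RMSD-binned decoy poses), bootstrapped accuracy metrics with
    confidence intervals, and a fully synthetic complex generator with
    known ground-truth bias structure for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    ChemmineOB,
    ChemmineR,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    ranger,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
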