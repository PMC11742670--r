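Package: frscreen
Title: Fuzzy-Rough Feature Selection and Convolutional IC50 Regression
    for Virtual Drug Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: A drug-repurposing screening toolkit built around quantitative
    structure-activity (QSAR) descriptor tables.  Fuzzy-rough-set machinery
    (graded similarity relations, lower/upper approximations, dependency
    degrees and greedy QuickReduct search) selects the molecular descriptors
    that govern the half-maximal inhibitory concentration (IC50) of a
    compound panel; a seeded one-dimensional convolutional network regresses
    IC50 on the selected descriptors; local linear surrogate explanations
    attribute individual predictions to binned descriptor ranges; and
    candidate libraries are ranked by ascending predicted IC50.  Seeded
    synthetic compound-library generators with planted relevant descriptors
    make every stage testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    ChemmineOB,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr,
    yaml
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
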