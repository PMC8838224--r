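Package: vanchar
Title: Characterization and QSAR Analysis of Oxidovanadium(IV) Complexes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-style toolkit for the physico-chemical characterization
    of oxidovanadium(IV) (vanadyl) coordination complexes. Covers molecular
    formula arithmetic for elemental analysis and thermogravimetric mass-loss
    assignment, the empirical V=O stretching-frequency to bond-length
    correlation, conceptual-DFT global reactivity descriptors from frontier
    orbital energies, Benesi-Hildebrand estimation of DNA binding constants
    with chromism classification, Coats-Redfern and Horowitz-Metzger
    decomposition kinetics, molar-ratio stoichiometry determination, and a
    four-descriptor multiple-linear-regression QSAR model. Includes seeded
    synthetic-data generators emulating each instrument output so the whole
    pipeline is testable without raw instrument files.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
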