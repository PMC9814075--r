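Package: aminescreen
Title: Virtual Screening of Tertiary Amines for CO2 Absorption
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A screening toolkit for aqueous tertiary-amine CO2 solvents. It
    combines a speciation-coupled kinetic rate model (acid-base equilibria
    solved on the pH axis, a Polanyi-Evans linear free-energy barrier and a
    Henry's-law CO2 feed), substructure-count molecular descriptors (shortest
    topological paths, atom pairs and atom triplets), a consensus QSPR
    workflow (random forest, gradient boosted trees and support vector
    regression over hyperparameter grids, repeated and nested cross-validation,
    Y-randomization and boundary-box applicability domains), SMILES
    standardization and structural screening filters, and data reduction for
    constant-interfacial-area gas-absorption (Lewis cell) experiments.
    Synthetic amine libraries and kinetic traces make the full pipeline
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineOB,
    bio3d,
    igraph,
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    ranger,
    xgboost,
    e1071,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    readr,
    yaml,
    optparse
Config/testthat/edition: 3
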