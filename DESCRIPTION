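Package: flavoqsar
Title: MLR-QSAR Modelling and Virtual Screening of Flavonoid
    Alpha-Glucosidase Inhibitors
Version: 0.1.0
Authors@R:
    person("flavoqsar", "maintainers", email = "maintainers@flavoqsar.org",
           role = c("aut", "cre"))
Description: A ligand-based pipeline for discovering natural
    alpha-glucosidase inhibitors among dietary flavonoids: SMILES parsing
    and canonicalization, topological (path/subgraph) and circular (ECFP)
    fingerprints with Tanimoto similarity and single-linkage clustering,
    2D molecular descriptors (Moreau-Broto autocorrelations, Basak
    information-content indices, Kier-Hall E-state atom types),
    genetic-algorithm descriptor selection for multiple-linear-regression
    QSAR models with a full leave-one-out validation suite, a
    similarity/drug-likeness virtual-screening funnel with activity
    prediction, an MMGBSA energy-decomposition auditor, and synthetic-data
    generators for all of the above.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
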