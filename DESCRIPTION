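Package: phoregen
Title: Quantitative Pharmacophore Modeling and Ligand-Based Virtual Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A ligand-based 3D-QSAR pharmacophore workflow for small-molecule
    inhibitor series: perception of typed chemical features (hydrogen-bond
    acceptor/donor, hydrophobic, ring aromatic) from conformer ensembles,
    HypoGen-style hypothesis generation (constructive, subtractive and
    simulated-annealing optimization phases) scored by a description-length
    cost model in bits, fit-value activity estimation calibrated by
    log-linear regression, a validation battery (activity scales, signed
    error values, log-scale correlation, Fischer randomization,
    leave-one-out), and a virtual-screening funnel with Lipinski and ADMET
    filters and Murcko-scaffold deduplication. Ships the activity tables of
    a published anoctamin-1 (ANO1) inhibitor series as fixtures and a
    synthetic feature-cloud generator with planted pharmacophores so every
    stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ChemmineR,
    ChemmineOB,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
SystemRequirements: OpenBabel (obabel on PATH); Python 3 with RDKit (for
    conformer generation)
Config/testthat/edition: 3
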