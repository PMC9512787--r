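Package: augminr
Title: Integrative Structural Analysis of the Augmin (HAUS) Complex
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for integrative analysis of coiled-coil multiprotein
    assemblies such as the augmin (HAUS) complex: ensemble flexibility
    profiling of predicted models via least-squares superposition,
    crosslinking mass-spectrometry validation against atomic models
    (score-based deduplication and filtering, Calpha distance-threshold
    satisfaction, per-subunit-pair summaries), rigid-body fitting of
    models into simulated electron densities scored by cross-correlation,
    composite-model splicing, and hinge (axis-angle) rotation measurement
    between conformations. Includes seeded synthetic-data generators
    (helix bundles, two-state hinge ensembles, flexible ensembles and
    crosslink tables with planted ground truth) so the whole pipeline is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
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
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
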