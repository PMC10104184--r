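Package: spgies
Title: Skeleton-Primed Greedy Interventional Equivalence Search for
    Gene-Network Recovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Causal structure learning for gene regulatory networks from
    mixed observational and interventional (gene-knockout) expression
    data.  Implements GIES-style greedy search with an interventional
    Gaussian BIC score, the SP-GIES two-step variant in which an
    observational skeleton estimator (PC, CLR or ARACNE) restricts the
    candidate edge set, a linear-Gaussian simulation benchmark on random
    network topologies with hard knockouts, evaluation metrics (SHD, SID,
    AUC-PR), and an optimal-experimental-design loop that chooses the
    next intervention target by bootstrap-posterior utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
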