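Package: fusionoverlap
Title: Overlap and Precision of Multi-Search Similarity-Based Virtual Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying what happens when many similarity searches are
    fused in ligand-based virtual screening. Generates synthetic fingerprint
    databases with activity classes of controllable homogeneity, scaffold
    structure and correlated fingerprint views; runs similarity-fusion and
    group-fusion search batteries with top-fraction cutoffs; computes search
    overlap and search precision profiles at molecule and scaffold level
    together with a binomial random-retrieval null; fits power-law, log-linear
    and cubic log-log trends to the profiles; and implements a
    preferential-attachment generative model of multi-search retrieval with a
    closed-form steady-state overlap recurrence, a Monte-Carlo simulator and a
    retrieval-weight estimator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Depends:
    R (>= 4.1)
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
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
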