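Package: trigame
Title: Tripartite Evolutionary Game Dynamics of Overtreatment Governance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates and analyses a three-population evolutionary game of
    excessive medical care: patients choosing whether to recognize treatment
    outcomes, healthcare institutions choosing between reasonable treatment and
    overtreatment, and government regulators choosing strict or lenient
    supervision. Provides the replicator dynamics of the three strategy
    frequencies, closed-form Jacobian eigenvalues and Lyapunov (indirect
    method) stability classification of the eight pure-strategy profiles,
    adaptive-step trajectory integration with vertex-convergence detection,
    multi-start basin exploration, one-parameter sensitivity sweeps, seeded
    generation of parameter regimes with prescribed stability structure, and a
    finite-population proportional-imitation simulator whose mean-field limit
    is the replicator flow. Results are tibbles with broom-style tidy() and
    glance() methods and ggplot2 autoplot() methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
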