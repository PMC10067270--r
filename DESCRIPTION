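Package: globalepi
Title: Global Epistasis Analysis of Combinatorial Fitness Landscapes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantify, predict, and decompose global epistasis in
    combinatorial fitness landscapes over binary loci. Provides a
    tibble-backed landscape container with tab-separated I/O, the
    Walsh (Fourier) interaction-coefficient expansion of a
    genotype-fitness map, per-mutation regressions of fitness effects
    on background fitness with pattern classification (diminishing
    returns, increasing costs, and related patterns), a decomposition
    of each regression slope into per-partner contributions from
    background-averaged pairwise epistasis and fitness effects, and
    simulators for additive, house-of-cards, sparse-pairwise, and
    nonlinear latent-variable landscape regimes, plus a command-line
    interface for reproducible runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    readr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
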