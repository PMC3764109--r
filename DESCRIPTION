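Package: hourglass
Title: Asymmetric Division and Dilution-Threshold Control of Cell Population Size
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for an hourglass (intrinsic-timer)
    model of cell population size control. A founder cell carries a cell-cycle
    factor that is diluted by asymmetric division: at each division a fraction p
    of the factor goes to one daughter and 1-p to the other, and a cell whose
    content falls below a threshold phi (as a fraction of the founder's content)
    permanently exits the cell cycle. The package grows deterministic and
    stochastic (binomial-partitioning) lineage trees, sweeps the (p, phi)
    parameter plane for final population sizes and growth-curve topologies,
    quantifies the confidence of final sizes under segregation noise, locates
    noise-robust ("special") population sizes across founder molecule counts,
    and measures sensitivity to per-division Gaussian perturbation of p and phi.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    ape,
    readr,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
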