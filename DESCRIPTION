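Package: twopartsim
Title: Two-Part Breeding Program Simulation with Optimal Cross Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Stochastic simulation of plant breeding programs that split
    population improvement (rapid recurrent genomic selection) from product
    development (doubled-haploid line pipeline with staged field trials),
    together with an optimal cross selection optimizer that balances genetic
    gain against group coancestry on a penalty-degrees scale. Includes
    ridge-regression genomic prediction with heterogeneous error variance,
    identity-by-state coancestry, and comparison metrics: standardized
    genetic gain, genic standard deviation, realized effective population
    size from genic-variance decay, and the efficiency of converting genetic
    diversity into genetic gain.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
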