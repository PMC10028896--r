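Package: alchrex
Title: Toy-Scale Alchemical Replica Exchange Free Energy Calculations with
    Sampling Diagnostics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Relative free energy calculations for toy particle systems using
    hybrid-topology alchemical potentials with softcore lifting, alchemical
    replica exchange (AREX), replica exchange with solute tempering (AREST),
    and multistate Bennett acceptance ratio (MBAR) estimation. Includes the
    accompanying sampling-diagnostics workflow: free energy time-series
    convergence testing, replica-mixing reports, statistical inefficiency,
    correlation of dU/dlambda with conformational degrees of freedom, and
    forward/reverse internal consistency. Built-in fixture generators provide
    analytic and brute-force oracles so every stage is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    rlang,
    generics,
    ggplot2
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
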