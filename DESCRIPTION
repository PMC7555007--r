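Package: synapsim
Title: Agent-Based Simulation of Immunological Synapse Formation and TCR
    Cooperativity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A kinetic Monte Carlo, agent-based model of immunological
    synapse formation between a T cell membrane and a supported lipid
    bilayer. Molecules (TCR, pMHC, LFA-1, ICAM-1) diffuse on paired 2D
    lattices with single-occupancy exclusion, bind and unbind with
    probabilities derived from molar on/off rates, and bound complexes are
    subject to size-based segregation and centripetal F-actin-driven
    transport. A three-state F-actin focus automaton on a third lattice
    feeds back on the TCR-pMHC association probability through a binding
    coefficient. The package computes the in situ dissociation constant
    cellKD = [TCRfree][pMHCfree]/[TCR-pMHC] and provides batch drivers for
    pMHC/TCR titrations, coupling-arrest experiments, and binding
    coefficient sweeps, returning tidy tibbles with broom-style tidiers
    and ggplot2 visualisations.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    generics,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    yaml,
    stats,
    grDevices,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
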