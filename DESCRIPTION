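Package: lamstack
Title: Monte Carlo Analysis of Interactions in Multilamellar Membrane Stacks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constant-pressure Metropolis Monte Carlo simulation of a periodic
    stack of undulating membranes interacting through hydration, van der Waals
    and short-range steric forces, together with the downstream analysis used
    in osmotic-stress experiments on multilamellar lipid systems: finite-size
    extrapolation of simulated observables, histogram reweighting for
    parameter derivatives, trust-region least-squares fitting of the hydration
    amplitude, hydration decay length and bending rigidity to pressure-distance
    and fluctuation isotherms, and decomposition of the total osmotic pressure
    into hydration, van der Waals and undulation components.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
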