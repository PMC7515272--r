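Package: mtepkin
Title: Steady-State Thermodynamics and Maximum Transitional Entropy
    Production for Enzyme Kinetic Cycles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Hill diagram (King-Altman spanning tree) solution of the
    stationary distribution of reversible enzyme kinetic schemes, with
    per-transition affinities, fluxes and entropy productions at the
    nonequilibrium steady state.  Implements maximization of a chosen
    transition's entropy production over its forward rate constant at
    fixed equilibrium constant (the maximum transitional entropy
    production, MTEP, theorem), joint iterative optimization of two
    transitions, catalytic constants from the diagram solution, and a
    light-driven extension for photocycles such as the bacteriorhodopsin
    proton pump (radiation-temperature equilibrium constants, secondary
    force cycle closure, quantum yield and force scans).  Ships kinetic
    scheme fixtures for beta-lactamase, triosephosphate isomerase, ATP
    synthase and bacteriorhodopsin models together with published
    reference observables, and a seeded generator of thermodynamically
    consistent random schemes for property testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
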