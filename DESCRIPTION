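Package: structglv
Title: Structured Plus Random Interactions in Generalized Lotka-Volterra Communities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying species-rich generalized Lotka-Volterra communities whose
    interaction matrix is the superposition of a low-rank structural component, built from
    species-level impact and sensitivity traits mediated by a few collective functions
    (functional groups, public goods, phylogenetic blocks), and an i.i.d. random component
    of tunable intensity. Provides builders for the structural archetypes, samplers for the
    random component, a stiff-capable simulator of the dynamics with an immigration floor,
    a solver for the closed macroscopic self-consistency equations at equilibrium
    (functional magnitudes, heterogeneity, diversity, truncated-Gaussian species abundance
    distributions), and stability diagnostics separating bulk-driven from structure-driven
    (outlier/Hopf) transitions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
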