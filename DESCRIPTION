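Package: bilayerperm
Title: Membrane Permeability from Unbiased Crossing Kinetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Computes passive membrane permeabilities of small molecules
    from unbiased particle trajectories crossing a lipid-bilayer-like
    barrier. Provides trans-bilayer free-energy profiles by Boltzmann
    inversion of position densities with block-averaged errors, barrier
    heights and Aniansson barrier widths, spontaneous crossing-event
    detection and Poisson rate estimates, mean-squared-displacement
    estimators for lateral lipid and solute normal diffusion, and a
    corrected Arrhenius model that extrapolates high-temperature crossing
    kinetics to physiological temperature using the temperature dependence
    of lipid diffusion and barrier width. A bundled overdamped Langevin
    trajectory generator with analytic mean-first-passage-time and flux
    oracles makes every stage testable without molecular-dynamics data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
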