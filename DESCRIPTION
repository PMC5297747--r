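Package: serpkin
Title: Branched Suicide-Substrate Kinetics of Serpin Protease Inhibition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation and estimation tools for the branched suicide-substrate
    mechanism by which serpins (serine protease inhibitors) inactivate their
    target proteases. Provides a mass-action forward model of the inhibitory
    and substrate pathways with chromogenic-substrate competition, a seeded
    generator of synthetic assay datasets (progress curves, stoichiometry-of-
    inhibition titrations, Michaelis-Menten initial-rate sets, temperature/pH
    stability profiles), and the standard estimator chain: nonlinear
    progress-curve fits for the pseudo-first-order inactivation rate k_obs,
    the k_obs-versus-inhibitor slope k_unc, the substrate-competition
    correction yielding the second-order association constant k_ass,
    x-intercept estimation of the stoichiometry of inhibition (SI), and
    Lineweaver-Burk or direct Michaelis-Menten fits. Also includes serpin
    sequence utilities: hinge-region alanine-motif detection, P1/P1' site
    transfer through a pairwise alignment, and covalent serpin-protease
    complex mass prediction.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    minpack.lm,
    stats,
    utils
Suggests:
    Biostrings,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
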