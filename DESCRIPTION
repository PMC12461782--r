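Package: chelkin
Title: Thermodynamics, Kinetics and Mechanisms of Metal-Ligand Complex Formation
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Turns coordination-state observables of metal-ligand complexes in
    aqueous solution into equilibrium association constants with Monte Carlo
    uncertainties, formation and dissociation rate constants via Markov state
    models with PCCA+ coarse-graining and transition path theory, a
    thermodynamic-kinetic decomposition of the chelate effect for bidentate
    ligands (open-ring/closed-ring two-step model), and an associative versus
    dissociative classification of water-ligand exchange events. Includes a
    fully specified synthetic-data generator (Gillespie continuous-time Markov
    chains, basin-structured free-energy surfaces, binding-event distance
    traces) with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Software, Kinetics, StatisticalMethod
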