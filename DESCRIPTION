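Package: memanchor
Title: Drug-Membrane Anchorage Metrics from Molecular Dynamics Trajectories
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies how small molecules anchor to lipid bilayer surfaces
    in molecular dynamics trajectories: per-leaflet residence times with a
    salt-bridge distance cutoff, geometric hydrogen-bond counting, diffusion
    coefficients from mean square displacements via the Einstein relation,
    mid-plane proximity, one-dimensional mass density and Boltzmann-inversion
    free-energy profiles, and block-averaged uncertainties.  A four-criterion
    categorical rubric turns per-drug metric bundles into an anchorage-based
    potential ranking.  A Brownian-dynamics generator produces synthetic
    membrane-adsorption trajectories with known ground truth (bulk
    diffusivity, adsorption well depth, equilibrium occupancy) so every
    estimator can be validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
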