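Package: steerBD
Title: Brownian Dynamics of Protein-Membrane Electrostatic Steering
Version: 0.1.0
Authors@R:
    person("steerBD", "Maintainers", email = "maintainers@steerbd.org",
           role = c("aut", "cre"))
Description: Rigid-body Brownian dynamics (Ermak-McCammon propagator) of a
    charged peripheral protein diffusing over model lipid bilayers that carry
    a central phosphoinositide (PIP3) charge plus configurable anionic
    "decoy" lipid charge distributions. Builds planar headgroup charge
    lattices under zwitterionic, even-fractional, random-subset and spatially
    clustered charge schemes; computes screened-Coulomb (Debye-Hueckel)
    potential grids and optional electrostatic desolvation grids; propagates
    trajectory ensembles from a truncated b-sphere to a q-surface with
    grid-derived forces and torques; and reduces ensembles to
    Jacobian-reweighted positional (r, d) and orientational (theta)
    steering statistics, Gaussian half-width fits, first-encounter
    distributions, and residue-phosphorus contact fingerprints.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
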