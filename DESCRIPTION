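Package: coronadsorb
Title: Polymer Adsorption Analysis on Protein Surfaces from Molecular Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trajectory analysis of short polymer chains (PEG, poly-sarcosine,
    poly-alanine and generic bead polymers) adsorbing on a protein surface.
    Provides topology/trajectory readers (PDB, DCD, XYZ), periodic-boundary
    geometry, surface-distance radial distribution functions, Langmuir
    isotherm fitting of shell polymer fractions, per-residue polymer/water
    affinity maps with OpenDX density-grid export, hysteresis-based
    adsorption/desorption event kinetics with lognormal summaries, polymer
    shape descriptors (end-to-end distance, radius of gyration, inertia-tensor
    aspect ratio), adsorption free energies from adsorbed/free densities with
    Monte-Carlo shell volumes, hydration and aggregation analyses, and
    diffusion coefficients from mean-square displacements. Two synthetic
    trajectory generators (a two-state Markov placement model with analytic
    ground truth and a Brownian-dynamics bead-spring simulator) supply
    datasets with known answers for validating every analysis stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    bio3d,
    minpack.lm,
    igraph,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
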