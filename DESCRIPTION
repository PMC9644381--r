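Package: asdtraj
Title: Trajectory Analysis of Protein-Stabilized Amorphous Solid Dispersions
Version: 0.1.0
Authors@R:
    person("ASD", "Tools Contributors", email = "asdtraj@example.org",
           role = c("aut", "cre"))
Description: Analysis of molecular-dynamics trajectories of amorphous solid
    dispersions in which a protein excipient stabilizes a small-molecule
    drug. Implements geometric hydrogen-bond detection with occupancy
    (existence) matrices and stability thresholds, tracing of hydrogen-bond
    network generations rooted at the protein, drug-shell spatial
    classification from protein-drug minimal distances, radial distribution
    functions, and per-molecule diffusivity estimation in the protein
    reference frame via mean-squared-displacement fits. Ships a
    Brownian-dynamics synthetic-trajectory generator with planted ground
    truth (diffusivities, hydrogen-bond schedules, shell structure) so every
    analysis stage is verifiable without running molecular dynamics, plus
    readers and writers for GRO coordinate series and an extended-XYZ
    dialect, a simulation-box composition planner, and a pipeline
    orchestrator with a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
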