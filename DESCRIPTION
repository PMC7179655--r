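Package: iescan
Title: Computational Alanine Scanning with MM/GBSA and Interaction Entropy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-state binding free energy analysis of protein-ligand
    molecular-dynamics trajectories. Implements single-trajectory
    computational alanine scanning with MM/GBSA energetics (gas-phase
    Coulomb and Lennard-Jones terms, OBC generalized-Born polar solvation
    with residue-class dielectrics, empirical SASA nonpolar solvation) and
    the interaction-entropy estimator of the entropic contribution, plus
    the trajectory analytics used to interpret the results: RMSD and
    2D-RMSD with Kabsch superposition, isotropic B-factors, hydrogen-bond
    occupancy, and center-of-mass distances. Includes seeded synthetic-data
    generators (toy host-guest complexes, parameterized energy series,
    planted hydrogen-bond trajectories) so every estimator is testable
    without external trajectories.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
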