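Package: confdyn
Title: Conformational Dynamics Analysis of Protein Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-simulation analysis of protein molecular dynamics
    trajectories aimed at detecting conformational transitions, with an
    emphasis on phosphorylation-induced changes in multi-domain enzymes
    such as DNA polymerase beta. Provides trajectory and topology readers
    (PDB, GRO, DCD), Kabsch least-squares superposition, RMSD / radius of
    gyration / RMSF time series and their probability distributions with
    peak detection, geometric hydrogen-bond and salt-bridge tracking with
    occupancies and moving averages, essential dynamics (Cartesian
    covariance analysis) with cosine-content screening of principal
    components and porcupine vector export, two-dimensional free-energy
    landscapes with basin extraction and representative-frame selection,
    dynamic cross-correlation matrices, and correlation-weighted residue
    interaction networks with degree, closeness and betweenness
    centralities and between-condition difference maps. Includes seeded
    synthetic-trajectory generators with planted statistical structure
    for validation, and a two-condition comparison pipeline producing a
    machine-readable report.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    bio3d
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
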