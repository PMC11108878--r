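Package: corrshuttle
Title: Correlated Shuttle-Motion Analysis for Cytochrome Domain Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trajectory analysis of correlated ("shuttle") motion of the two
    membrane-anchored cytochrome (PscC) domains relative to the P840 special
    pair of the green-sulfur-bacterial type-I reaction center. Provides a
    mutually-exclusive distance-occupancy statistic swept over a threshold d
    and contraction factor C, distance-distribution mode analysis,
    RMSD/RMSF flexibility profiling with Kabsch superposition, and
    graph-theoretic correlation-pathway extraction, together with a synthetic
    trajectory generator (Ornstein-Uhlenbeck fluctuations with two-state
    Markov switching, and planted residue-correlation networks) that supplies
    analytic ground truth for every analysis stage.
License: MIT
Encoding: UTF-8
Imports:
    bio3d,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
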