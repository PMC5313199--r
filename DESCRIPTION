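Package: bpremd
Title: Repulsive-Bias Hamiltonian Replica-Exchange Docking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Flexible ligand-receptor binding-site search by Hamiltonian
    replica-exchange molecular dynamics with a repulsive biasing potential.
    The collective variable is an inverse-power (1/d^12) weighted mean
    distance between surface-atom groups of the two binding partners;
    per-replica penalty windows transiently push the ligand off the receptor
    surface in higher replicas while Metropolis exchanges funnel favourable
    contact geometries into an unbiased reference replica. Includes a
    coarse-grained Langevin (BAOAB) engine with harmonic restraint schemes,
    synthetic sticky-surface docking systems with a certified native site,
    and trajectory analysis (ligand RMSD after receptor superposition,
    near-native fractions, leader clustering, interaction-energy profiles,
    first-passage times).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
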