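Package: dnacage
Title: Polyamine Caging and Interaction Analysis for Parallel DNA Duplexes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trajectory analysis of polyamine counterions confined between
    parallel DNA double helices. Provides region-resolved radial distribution
    functions and coordination numbers, inter-duplex phosphate contact mapping,
    El Hassan-Calladine minor/major groove widths with periodicity detection,
    a geometric caged/uncaged state classifier with residence statistics,
    end-to-end conformational classification of flexible polycations, and
    detection of phosphate-bridging interaction modes. Includes a synthetic
    structure and trajectory generator (fiber-model B-DNA, two-duplex
    assemblies, nucleosome-like superhelical DNA, two-state Markov exchange
    dynamics) so the full pipeline runs without external molecular dynamics
    data. Structures and trajectories are read and written as PDB, multi-model
    PDB, and CHARMM DCD.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    jsonlite,
    stats,
    graphics,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
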