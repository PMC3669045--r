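Package: pairforce
Title: Pairwise Force Distribution and Punctual Stress Analysis for
    Molecular Dynamics Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Recomputes internal forces over a previously generated
    molecular dynamics trajectory (a "rerun") and decomposes them into
    antisymmetric vector pairwise forces between atoms, including an exact
    decomposition of the 3- and 4-body bonded potentials (angles, proper
    and improper dihedrals, cross bond-bond and cross bond-angle terms).
    Pairwise forces are aggregated into residue-residue forces, signed
    scalar pairwise forces (attractive/repulsive), per-atom and per-residue
    punctual stress, and per-frame summaries, all streamed to simple text
    time-series files.  Ships readers for GRO/XYZ trajectories, GROMACS
    NDX index groups and a documented flat-text topology format, plus
    deterministic toy-system generators and a Langevin force-clamp
    integrator so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    optparse,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
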