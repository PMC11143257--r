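Package: poreflux
Title: Ion Permeation, Occupancy, Contact-Network and Metadynamics Analysis of Channel MD Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Turns molecular dynamics trajectories of membrane ion channels
    into the quantities used to characterise selectivity-filter gating:
    complete ion permeation events and single-channel conductance, axial and
    radial ion occupancy profiles with binding-site assignment, backbone psi
    dihedral flip statistics, helix orientation angles against a reference
    structure, representative-atom residue contact probabilities and
    state-difference maps, correlation-filtered protein structure network
    shortest paths, well-tempered metadynamics free-energy surface
    reconstruction from hills logs, adiabatic-bias force bookkeeping, and
    Hill-equation dose-response fitting. A seeded synthetic-trajectory
    generator with planted ground truth makes every stage testable at desk
    scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    igraph,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
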