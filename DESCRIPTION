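Package: slitdyn
Title: Hydrogen-Bond Kinetics and Jump-Diffusion Decomposition for Nanoconfined Water Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for molecular-dynamics trajectories of water under
    planar nanoconfinement (graphene-like slit pores) and in the bulk. Classifies
    every O-H bond per frame as hydrogen-bonded (HB) or dangling (DB) with a
    configurable geometric criterion, computes continuous survival correlation
    functions and lifetimes of both states, tracks stable solvation-shell
    compositions after transient filtering, detects solvation-water-exchange
    (SWE) and intra-shell "kick" events with interpolated time origins, and
    decomposes the translational diffusion coefficient into frame, SWE and kick
    contributions through a continuous-time random-walk model. Ships synthetic
    trajectory generators (two-state telegraph bond kinetics, jump+drift
    continuous-time random walks, toy quasi-2D monolayer and 3D bulk water with
    planted events) so every detector and estimator is testable against known
    ground truth. Reads and writes multi-frame extended-XYZ and reads PDB
    frame sequences with periodic cell support.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
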