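Package: shoaldyn
Title: Collective Movement of Fish Shoals from Consistent Individual
    Differences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation and trajectory analysis of small fish shoals whose
    members differ consistently in speed and goal-orientedness.  Provides a
    zonal (repulsion/orientation/attraction) self-propelled-particle model
    with heterogeneous agents, in a periodic free-schooling arena or a
    circular foraging arena with depletable food patches; per-individual
    kinematics from discrete tracking data (Savitzky-Golay smoothing,
    finite-difference velocity, heading, acceleration, turning speed);
    group-referenced geometry and order parameters (nearest-neighbour
    distance, centre distance, group-frame transform, front occupancy,
    cohesion, polarization); frame-wise schooling classification with a
    threshold robustness scan; delay-correlation leadership network
    inference; and foraging analytics (patch discovery, depletion
    latencies, cover occupancy, individual behavioural scores).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    signal,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
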