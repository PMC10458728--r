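Package: flytunnel
Title: Flight-Tunnel Monitoring of Insect Visual-Motor Coordination with Dynamic Obstacles
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Simulation and analysis pipeline for monitoring insect
    visual-motor coordination in a flight tunnel with a dynamically moving
    obstacle gap. Provides the tunnel scene and barrier kinematics model, a
    seeded synthetic renderer for detector (30 fps) and high-speed (163 fps)
    camera sequences, a direction-gated motion trigger based on background
    subtraction and centroid displacement, per-frame pose (centroid, yaw) and
    gap-width extraction, planar virtual mapping of pixel tracks into world
    coordinates, geometric optic-flow reconstruction over a spherical
    ommatidial field by ray casting, retinal-expansion statistics (retinal
    size, its rate, and relative retinal expansion velocity), and
    simulation-based evaluation harnesses (speed-adaptability sweep, mapping
    round-trip error, acquisition accuracy, trajectory statistics).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    png,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
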