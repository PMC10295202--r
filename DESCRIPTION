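Package: dotpulse
Title: Segmentation, Physiology Retrieval and Simulation of Dissolved
    Oxygen Pulses in Intermittently Fed Minibioreactors
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for analysing dissolved oxygen tension (DOT) traces from
    E. coli minibioreactor cultivations with intermittent bolus feeding.
    Detects the negative DOT pulse that follows each glucose bolus, labels up
    to four physiologically meaningful segments per pulse (glucose oxidation
    with overflow, metabolic adaptation, acetate oxidation, transfer-driven
    recovery), and retrieves reactor and cell-physiological parameters (KLa,
    qO2max, oxygen yields on glucose and acetate, OUR) from the segment
    geometry.  Includes first-order sensor-lag inversion, an event-driven
    piecewise metabolic simulator with an explicit adaptation state, and a
    synthetic-experiment generator so the complete analysis loop can be
    exercised without laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
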