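Package: coppertracks
Title: Quantification of Copper-Barrier Sensory-Integration Worm-Tracking Assays
Version: 0.1.0
Authors@R: person("Plate", "Imaging Lab", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying C. elegans behavior in the copper-barrier
    sensory-integration assay from tracker-exported midpoint trajectories.
    Implements track exclusion filters, classification of barrier-terminating
    tracks into forward/reverse/reversal categories, cumulative net
    barrier-crossing scores, residence-probability and velocity profiles in
    1 mm bins of signed distance from the barrier, the chemotactic index,
    and per-bin group comparisons with Welch's t-tests and Holm-Sidak
    multiplicity correction. Includes a persistent-random-walk simulator
    that generates track sets with known ground truth (crossing events,
    planted degenerate tracks, speed-versus-distance laws) for validating
    every analysis stage, plus command-line entry points for analysis,
    simulation and group comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, grDevices, graphics, tools, jsonlite
Suggests: testthat (>= 3.0.0), optparse, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
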