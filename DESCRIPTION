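Package: crowdcaps
Title: Capsule Networks with Recurrent Routing as Models of Visual Crowding and Uncrowding
Version: 0.1.0
Authors@R: person("crowdcaps", "developers", role = c("aut", "cre"),
    email = "crowdcaps@example.org")
Description: Procedural generation of vernier and flanker stimuli, capsule
    networks with recurrent routing-by-agreement trained from scratch
    (convolutional feature extraction, primary/secondary capsules, margin and
    decoder losses), matched feedforward and recurrent control architectures,
    an (un)crowding test protocol with routing-iteration sweeps and the
    associated statistics, and a psychophysics toolbox (PEST adaptive
    staircase, cumulative-Gaussian threshold estimation, simulated 2AFC
    observers).  All networks are implemented in base R linear algebra with
    hand-derived gradients, so the full pipeline runs on one CPU without a
    deep-learning framework.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
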