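Package: gammareach
Title: Movement-Related Gamma Oscillations and Reaching Kinematics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis pipeline linking movement-related
    gamma-band EEG dynamics to reaching-movement kinematics. Provides a
    synthetic-data generator for epoched scalp EEG with injected
    oscillatory bursts and phase-lagged coupling, minimum-jerk reaching
    trajectories, Morlet wavelet time-frequency decomposition with
    whole-epoch baseline normalization, cluster-based permutation
    statistics with sensor adjacency, the debiased squared weighted phase
    lag index, Network Based Statistics over connectivity matrices,
    mixed-effects modelling of movement extent, and regression screens
    relating gamma power and phase synchronization to peak velocity and
    movement time.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    lme4,
    lmerTest,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
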