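Package: gaitphase
Title: Gait-Phase Detection from a Single Foot Gyroscope with Hidden Markov Models
Version: 0.1.0
Authors@R: person("Gait", "Lab", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Automated segmentation of the gait cycle into stance, heel-off,
    swing and heel-strike from a single sagittal-plane foot gyroscope. A
    four-state left-right hidden Markov model is trained without operator
    intervention from one trial labelled by force-sensitive-resistor (FSR)
    foot switches, then decoded offline with the Viterbi algorithm or
    causally, sample by sample, with the forward algorithm. Includes the
    FSR reference labeller, tolerance-windowed sensitivity/specificity
    scoring, a synthetic gait simulator (typical and toe-walking gait,
    walking and non-walking tasks), and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
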