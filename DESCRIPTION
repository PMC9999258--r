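Package: telerehab
Title: Wearable Remote Rehabilitation Training: Simulation, Scoring, and
    Trial Design
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Software core of a wearable remote rehabilitation training
    system for stroke motor rehabilitation. Generates ground-truth-labeled
    synthetic 30 Hz inertial and data-glove sensor streams; preprocesses
    them (sliding filter, headless-mode orientation rebasing) and segments
    repetitions; extracts per-repetition motion features (amplitude, mean,
    root-mean-square, normalized jerk, grip strength); scores repetitions
    against standard-movement templates with difficulty thresholds and a
    game-score accumulator; manages the 16-exercise catalog and once-daily
    difficulty adaptation; and implements the companion trial-design
    computations (noninferiority sample size, dropout inflation, stratified
    block randomization, Fugl-Meyer assessment totals, summary-statistics
    confidence intervals and two-sample and proportion comparisons).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    zoo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
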