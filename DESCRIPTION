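Package: falltime
Title: Temporal Verification of Fall and Lean-Over Incidents from Wearable
    Altimeter Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Distinguishes involuntary falls from voluntary lean-over (bend)
    movements in height-time trajectories recorded by wearable altimeters,
    as worn by elderly people in smart homes. Implements two temporal
    inference classifiers: a static threshold on the total descent time at
    the midpoint of the class mean durations (CM-I), and an incremental
    majority-vote classifier that compares the trajectory's crossing time at
    each height checkpoint against fall and lean-over reference times
    (CM-II), including a streaming variant. Ships a kinematic simulator of
    labeled descent incidents with class-conditional truncated-normal
    durations, an evaluation harness with repeated stratified k-fold
    cross-validation, accuracy metrics, and McNemar's paired test, plus CSV,
    JSONL and JSON model input/output and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
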