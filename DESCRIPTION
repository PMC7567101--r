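Package: oetsched
Title: Model-Based Adaptive Practice Scheduling with Optimal Efficiency Thresholds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying adaptive scheduling of spaced retrieval
    practice. Implements a two-component power-decay logistic model of
    recall (separate success and failure traces with shared spacing
    curvature), an exponential latency model linking predicted log-odds to
    correct-response time, a microeconomic expected-utility calculus of
    practice efficiency, conventional and heuristic practice schedules
    (massed, uniform, expanding, contracting, blocked, Drop-1), an
    optimal-efficiency-threshold (OET) item-selection policy, a
    clock-accurate session simulator with delayed final tests, maximum
    likelihood fitting of both models from trial-level logs, a synthetic
    trial-log generator for parameter-recovery studies, and condition
    analytics. A command-line front end ties the pieces into a
    reproducible pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Matrix,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
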