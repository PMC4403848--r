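Package: tugseg
Title: Detection and Segmentation of Timed-Up-and-Go Activities from
    Body-Worn Inertial Sensors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Automated detection and segmentation of the activities of a
    Timed-Up-and-Go (TUG) trial (Standing, Walking, Turning, Sitting) from
    multi-site inertial recordings sampled at 60 Hz.  Implements
    frequency-domain ideal band-pass signal conditioning, peak-based
    activity detection with 30%-threshold indicator signals, first-extremum
    transition segmentation into six segments and seven transition
    timestamps, quaternion joint range-of-motion computation, and
    exhaustive-search calibration of per-channel high-cut frequencies
    against reference transition times.  Includes a synthetic TUG trial
    simulator with ground-truth labels for testing and calibration, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    data.table,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
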