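Package: atas
Title: Automatic Temporal Analysis of Speech
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Detects pause and vocal events in continuous-speech recordings by
    adaptive short-time energy and zero-crossing-rate thresholding, computes a
    panel of thirteen temporal fluency metrics (speech rate, pause time, pause
    and vocal counts, durations and their variability, with separate short and
    long pause statistics), fits group-comparison generalized linear models
    with assumption-driven family selection and false-discovery-rate control,
    and trains feature-based and event-sequence group classifiers. Ships
    synthetic audio and cohort generators with ground-truth annotations so the
    whole pipeline is testable without recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    lmtest,
    rpart,
    randomForest
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    car
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
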