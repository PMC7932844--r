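Package: chronoperf
Title: Chronobiological Analysis of In-the-Wild Cognitive Performance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Scores smartphone-based alertness (psychomotor vigilance) and
    cognitive-throughput (addition test) sessions, derives chronotype,
    sleep-debt and sleep-shift metrics plus momentary heart-rate and
    activity features from wearable-style records, and quantifies their
    associations with repeated-measures correlation (ANCOVA common slope)
    and 24-hour single-component cosinor models.  Includes a seeded
    two-process (circadian plus homeostatic) synthetic cohort generator so
    the full pipeline is testable end to end without any external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
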