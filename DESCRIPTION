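Package: fixsens
Title: Microsaccade-Locked Modulation of Contrast Sensitivity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how visual contrast sensitivity changes around
    microsaccades during fixation. Provides a seeded synthetic-session generator
    (binocular gaze traces with drift, main-sequence microsaccades, blinks, and
    interleaved 1-up-3-down staircases driving a simulated observer), blink
    masking and velocity computation, median-based velocity-threshold
    microsaccade detection with binocular and amplitude filters, maximum-
    likelihood psychometric fitting with a global fixed-lapse protocol,
    time-resolved sensitivity timecourses with subject-matched baselines,
    bootstrap and permutation inference, box-counting drift quantification, and
    a delayed divisive-normalization gain model acting across spatial-frequency
    channels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
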