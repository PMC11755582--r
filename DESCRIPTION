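Package: fasciatrack
Title: Semi-Automated Muscle Tracking and Thickness Measurement for
    Abdominal Ultrasound Video
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for measuring the thickness of the lateral abdominal
    muscles (external oblique, internal oblique, transversus abdominis)
    in B-mode ultrasound video. An initial frame is segmented by a
    Viterbi brightest-path search for the four bounding fasciae, the
    segmentation is propagated to every frame with optical-flow
    tracking, and three measurement points per muscle are followed with
    a pyramidal Lucas-Kanade tracker. Calibrated thickness traces,
    automatic contraction-phase detection, the preferential activation
    ratio (PAR) and the associated group statistics (repeated-measures
    ANOVA with Mauchly's sphericity test and Greenhouse-Geisser
    correction, paired t-tests with Cohen's d, Mann-Whitney U) are
    provided, together with a seeded synthetic ultrasound-video
    generator for end-to-end validation without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
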