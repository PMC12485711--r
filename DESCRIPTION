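Package: photofed
Title: Fiber Photometry and Operant Feeding Behavior Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis of dual-channel fiber photometry recordings and
    home-cage operant feeding (FED3) event logs. Provides isosbestic
    motion correction by linear regression, dF/F0 and z-score
    normalization with explicit baseline windows, trailing-mean
    smoothing, threshold-crossing time-constant estimation of
    food-evoked falls and fasting-evoked rises in neural activity,
    peri-event alignment of activity to nose pokes and feeding events,
    Zeitgeber-time windowing, extinction-session summaries, a
    Holm-Sidak step-down adjustment utility, and a synthetic-data
    generator that produces photometry recordings and behavior logs
    with known ground truth for end-to-end verification.
License: MIT + file LICENSE
Encoding: UTF-8
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
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
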