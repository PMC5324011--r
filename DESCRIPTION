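Package: myoassess
Title: Two-Channel Surface EMG Controllability Assessment and Game Control
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a two-channel surface electromyography (EMG)
    controllability assessment battery for myoelectric control training:
    maximum voluntary contraction (MVC) calibration, precision control
    against randomized goal activation levels, electrode separation
    (cocontraction detection at a fixed threshold), and endurance control
    by retracing a slow reference sine with a bipolar composite of the two
    normalized channels, scored as windowed coefficients of determination.
    Includes an EMG-to-keyboard control mapper with hysteresis activation
    detection and cocontraction-based degree-of-freedom switching, a
    synthetic two-channel envelope simulator standing in for human
    participants (noise, bias, lag, opposing-channel leak, fatigue, and
    between-session learning), and the three-session statistical
    comparison pipeline (Shapiro-Wilk normality gating, Bonferroni
    corrected paired t tests, Wilcoxon signed-rank tests).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    ggplot2,
    rlang
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
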