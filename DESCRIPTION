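Package: pttbp
Title: Cuffless Blood Pressure Estimation from Pulse Transit Time
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Beat-to-beat pulse transit time (PTT) extraction from paired
    ECG and photoplethysmogram (PPG) waveforms, and cuffless blood pressure
    estimation with a compensated linear model that augments the classical
    PTT-BP line with PTT variation (VPTT) and PTT variability (PTTV) terms.
    Includes a two-posture (sitting/standing) hydrostatic calibration that
    personalises the model per subject, the measurement-acceptance rules of
    the oscillometric reference protocol, Bland-Altman and correlation
    agreement analysis, and a seed-controlled synthetic cohort generator
    that renders coupled ECG/PPG/BP sessions with known ground truth so the
    whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
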