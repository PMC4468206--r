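Package: murisomnia
Title: Murine Polysomnography Simulation and Sleep-Wake Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Epoch-based analysis of mouse EEG/EMG polysomnography: rule-based
    vigilance-state scoring on 5-second epochs, normalized spectral band
    analysis, sleep-architecture metrics (state percentages, bout durations,
    transition counts, hourly time courses), sleep-deprivation rebound
    quantification, pharmacological treatment-window analysis, ELISA
    normalization, and the accompanying ANOVA battery. A semi-Markov
    hypnogram and signal generator with planted group effects makes every
    stage of the pipeline testable end to end without animal recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    yaml,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    car,
    withr
Config/testthat/edition: 3
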