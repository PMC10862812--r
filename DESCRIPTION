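Package: stopphys
Title: Simulation and Analysis of Stop-Signal Task TMS/EMG Physiology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulates dual manual/vocal choice stop-signal tasks under an
    independent horse-race model with adaptive stop-signal-delay staircase
    tracking, and synthesizes per-trial transcranial magnetic stimulation (TMS)
    electromyography (EMG) traces whose motor-evoked-potential amplitudes follow
    a parameterized pause-then-cancel model of action-stopping. Provides the
    matching measurement pipeline: vocal response-onset detection, stop-signal
    reaction time by the integration method, peak-to-peak MEP amplitude
    extraction with the standard rejection and trimming rules, baseline-
    normalized corticospinal excitability, short-interval intracortical
    inhibition, cortical silent period detection, and per-participant
    effect-size profiles with classification of suppression timing
    (global-then-selective and related categories).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
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
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
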