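Package: sleepssd
Title: Scheduled Sleep Deprivation Analysis for Drosophila Activity Monitor Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying circadian modulation of sleep homeostasis in
    Drosophila with scheduled sleep deprivation (SSD) protocols. Reads and
    writes Trikinetics DAM monitor files, scores sleep from one-minute
    beam-crossing counts with the five-minute inactivity rule, constructs
    ultradian (7 h cycle) and abridged deprivation schedules, computes
    per-fly per-episode rebound metrics (sleep lost, sleep gain, deprivation
    efficiency, latency) with the >90% efficiency inclusion filter, builds
    circadian activity eductions, anticipation indices and rebound/baseline
    heatmaps with circular interpolation, and runs matched morning/evening
    statistical comparisons. Includes a bout-based (renewal) synthetic fly
    generator with a circadian gate, a sleep homeostat, mechanical
    stimulation response, and controllable time-of-day rebound gain
    injection, so every pipeline stage can be verified without raw data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
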