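Package: binlat
Title: Binaural Lateralization Assessment After Stroke
Version: 0.1.0
Authors@R:
    person("binlat", "maintainers", email = "binlat@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying binaural perception from headphone
    lateralization experiments and tone-in-noise detection tasks, aimed at
    clinical cohorts tracked over several measurement phases (e.g. acute,
    subacute and chronic phase after ischemic stroke).  The package scores
    trial-level 9-key lateralization responses into a fixed 31-metric
    profile (side-wise slopes, biases, variability, perceived ranges,
    monaural and extreme-cue percepts), builds order-statistic normative
    ranges from a control cohort, counts per-metric divergences and
    classifies overall lateralization normality, expresses longitudinal
    change in control-dispersion units with a toward/away sign convention,
    simulates one-up/three-down adaptive tone-in-noise tracks with binaural
    masking level difference (BMLD) extraction, computes pure-tone-average
    (PTA3) summaries, and generates fully seeded synthetic cohorts of
    control-like and impaired listeners so that every pipeline stage is
    testable without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    grDevices,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
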