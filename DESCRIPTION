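Package: flysleepr
Title: Sleep Depth, Arousal, and Metabolic Downscaling Analysis for Fly
    Activity Monitoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for behavioural sleep analysis in Drosophila from
    activity-monitor beam-cross counts: sleep-bout scoring under the 5-minute
    immobility rule, per-phase sleep architecture and waking-activity metrics,
    two-state Markov wake/doze transition-propensity estimation, arousal
    threshold and reactivity scoring from mechanical-stimulus assays,
    sleep-bout-aligned indirect-calorimetry percent-change statistics, and the
    ordinary-least-squares slope and ANCOVA inference used to compare
    genotypes. Includes readers and writers for monitor files, stimulus logs
    and VCO2 tables, and a seeded synthetic-cohort generator with control-like
    and Nf1-like parameter presets so every stage of the pipeline can be
    verified against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
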