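Package: eesmap
Title: Mapping Lower Urinary Tract and Hindlimb Responses to Epidural
    Spinal Cord Stimulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for stimulation-locked multichannel
    electrophysiology recorded during epidural electrical stimulation of
    the spinal cord: stimulus-triggered averaging of evoked potentials
    with first-peak latency and peak-to-peak amplitude measurement,
    recruitment-curve construction with linear-regression slope fitting
    up to the curve maximum, per-animal slope normalization and
    site-by-channel segment maps, percent-of-background quantification of
    5 Hz burst stimulation, and exact small-sample nonparametric tests
    (Wilcoxon signed-rank, Mann-Whitney, Kruskal-Wallis with Dunn's post
    hoc) implemented by full-distribution enumeration. Includes a seeded
    synthetic-recording generator with known ground truth so the whole
    pipeline is testable without raw recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    graphics,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
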