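Package: cortstate
Title: Cortical State Segmentation and State-Dependent Firing Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools to segment extracellular cortical recordings into
    synchronized and desynchronized states from low-frequency (0-7 Hz)
    local field potential power, detect up and down phases from pooled
    multiunit activity, classify spike-sorted units into putative
    pyramidal and fast-spiking classes from waveform features, estimate
    unit depth on laminar probes, and quantify state-dependent firing
    rate and burst modulation with the accompanying statistics
    (modulation index, per-cell t-tests, signed-rank and rank-sum
    population tests, semi-logarithmic rate-versus-modulation
    regression).  Includes a laminar recording simulator that produces
    ground-truth-annotated synthetic datasets for validating every
    stage of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
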