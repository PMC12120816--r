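Package: hipposlice
Title: Quantification of Hippocampal Slice Electrophysiology and Synapse Morphometry
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Detection and quantification of spontaneous sharp-wave ripples
    (SWR) in CA1 local field potentials, carbachol-induced gamma oscillation
    metrics with slice exclusion rules, fEPSP slope / input-output /
    paired-pulse / LTP analysis, rule-based dendritic spine classification
    with density and hierarchical aggregation, ROI intensity quantification,
    and two-channel synaptic puncta colocalization. Ships synthetic-data
    generators with known ground truth for every input type, a
    normality-gated two-group comparison, and an end-to-end synthetic cohort
    pipeline, so every stage is verifiable without external recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
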