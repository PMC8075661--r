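Package: dfcpattern
Title: Dynamic Functional Connectome Patterns from ROI Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extraction and group comparison of dynamic functional connectome
    patterns (DFCPs) from multi-subject regional fMRI time series. Computes
    sliding-window dynamic functional connectivity, per-window connectivity
    strength profiles, automatic segmentation of the strength time course
    into quasistable epochs, and whole-brain quasistable connectome pattern
    (WQCP) samples; clusters pooled WQCP samples by hierarchical-initialized
    K-means with Davies-Bouldin model selection; classifies patterns as
    group-specific or general from per-subject occupancy ratios; tests
    edgewise group differences with Bonferroni-style thresholds; and extracts
    critical regions by degree and participation-coefficient AUC over
    proportional graph thresholds. Includes a state-switching multivariate
    Gaussian cohort simulator with planted connectivity states for method
    validation, a bundled 246-region atlas lookup table, and exporters for
    BrainNet Viewer node/edge files.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    utils,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
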