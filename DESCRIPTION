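Package: overnet
Title: Overlapping Functional Brain Networks from Multimodal Imaging Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects overlapping functional networks in regional brain-imaging
    time series using an assortative mixed-membership stochastic blockmodel
    fitted by stochastic variational inference, with seed-consensus alignment
    (k-means plus Hungarian assignment), hierarchical run/session/animal
    aggregation, node-level overlap statistics (membership entropy, belonging
    counts, tiers, degree variants, participation coefficient), diffusion-map
    connectivity gradients, and hierarchical bootstrap inference with BCa
    intervals. Includes synthetic generators for benchmark graphs (sampled
    mixed-membership graphs and overlapping LFR-style graphs) and for
    hierarchical multi-animal datasets with planted community structure, so the
    full pipeline can be exercised and calibrated without restricted-access
    recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    signal,
    igraph,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
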