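Package: spinedyn
Title: Quantification of Dendritic Spine Morphology, RNA-Granule Transport
    and Spine Turnover
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale quantification tools for neuronal imaging studies:
    ratio-based morphometric classification of dendritic protrusions
    (mushroom, stubby, thin, filopodium) and per-dendrite spine densities;
    classification of kymograph-derived granule trajectories into five
    motion categories (stationary, oscillatory, bidirectional, anterograde,
    retrograde) with motility metrics (travel distance, maximal run length,
    maximal velocity); longitudinal spine turnover analysis (formation,
    elimination, survival and re-formation in proximity) from multi-day
    imaging; binned mRNA-puncta distributions along dendrites; and
    behavioral/electrophysiological summary scores (discrimination and
    social preference indices, marble burying score, LTP magnitude,
    paired-pulse ratio). Seeded synthetic-data generators with ground-truth
    labels make every stage testable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    readr,
    rlang,
    jsonlite,
    withr,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
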