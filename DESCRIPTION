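Package: vegrisk
Title: Dietary Health-Risk Assessment of Trace Elements in Leafy Vegetables
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Turns per-sample trace-element concentration tables for
    foodstuffs (mg/kg dry weight) into deterministic dietary health-risk
    indices (estimated daily intake, target hazard quotient, hazard index),
    FAO/WHO maximum-permissible-limit screening with fold-exceedance ratios,
    per-site tie-corrected Spearman rank-correlation matrices, and seeded
    Monte Carlo estimates of the probability that a heterogeneous consumer
    population exceeds health-based intake limits. Ships a built-in metal
    registry (oral reference doses, food limits, intake limits), a packaged
    survey dataset of Brassica pekinensis leaves from two urban gardening
    sites, analytical quality-control helpers (certified reference material
    recovery, limit-of-detection flagging), and a synthetic-data generator
    with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
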