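Package: hotspotr
Title: Habitat Models and Multi-Taxa Hotspot Maps for Marine Predators
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to turn animal tracking data and at-sea strip-transect
    surveys into model-averaged habitat suitability maps and multi-taxa
    overlap statistics on a standard 0.25 degree monthly grid. Includes
    trajectory cleaning (iterative speed filter, trip splitting, cadence
    resampling), kernel utilization distributions, presence/pseudo-absence
    construction, random-intercept binomial GLMMs over all covariate
    subsets with AIC ranking and Akaike-weight model averaging, repeated
    split cross-validation with AUC, ROC threshold selection, per-taxon
    suitability binarization, a 0-4 multi-taxa suitability index, and
    pairwise spatial overlap. A synthetic-data module generates seascapes,
    central-place-forager tracks and strip-transect surveys with known
    occupancy coefficients so the whole pipeline can be exercised by
    parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    geosphere,
    jsonlite,
    lme4,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
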