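Package: wingmorph
Title: Wing Geometric Morphometrics for Mosquito Identification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Landmark-based geometric morphometrics for insect wing
    identification: generalized Procrustes superimposition, centroid-size
    statistics, permutation tests for allometry, linear discriminant
    classification with leave-one-out cross-validation, canonical variate
    analysis with Mahalanobis distances, neighbor-joining trees with
    bootstrap support, observer-error and landmark-sampling diagnostics,
    and a compact COI maximum-likelihood validation stage (HKY+Gamma,
    AIC model selection). Includes a synthetic-data generator that
    emulates digitized wing-landmark datasets with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    MASS,
    phangorn,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
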