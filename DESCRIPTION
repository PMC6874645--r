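Package: ecpredict
Title: Early Colorectal Cancer Prediction from Clinical Case Reports
Version: 0.1.0
Authors@R: person("ecpredict", "maintainers", email = "maintainers@example.org",
    role = c("aut", "cre"))
Description: A four-stage pipeline for predicting early-stage colorectal
    cancer from routine clinical case-report tables: per-column Z-score
    standardization with nonnegativity restoration, nonnegative matrix
    factorization (Lee-Seung multiplicative updates) for dimensionality
    reduction, a deep belief network (stacked restricted Boltzmann
    machines trained by contrastive divergence, then fine-tuned by
    back-propagation) for feature extraction, and a linear support vector
    machine trained in the dual as the final classifier. Includes the
    stratified repeated-split evaluation protocol with accuracy,
    precision, recall, F1 and false-negative-rate reporting, a latent
    dimension sweep, an attribute-feature weight report, and a seeded
    synthetic clinical-table generator with planted low-rank structure
    standing in for private hospital records.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
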