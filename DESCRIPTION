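Package: hospeval
Title: Composite-Indicator Performance Evaluation of Hospitals with
    Entropy-Weighted TOPSIS and a Neural-Network Surrogate
Version: 0.1.0
Authors@R:
    person("hospeval", "maintainers", email = "hospeval@example.org",
           role = c("aut", "cre"))
Description: Builds composite performance scores for hospitals from a
    three-level indicator hierarchy: tendency treatment maps benefit, cost
    and interval indicators onto a common bigger-is-better [0,1] scale;
    level-1/2 weights come from analytic-hierarchy-process (AHP) pairwise
    comparisons and level-3 weights from the entropy-weight method; the
    weighted TOPSIS relative approach degree C_i ranks the hospitals.  A
    single-hidden-layer backpropagation network trained with a
    Levenberg-Marquardt solver serves as a fast surrogate for the composite
    score, selected by leave-one-out cross-validation and benchmarked
    against a partial least-squares regression baseline.  Ships the
    published Hubei 4/11/41 indicator system as a packaged configuration
    and a synthetic-data generator (latent hospital quality plus noise) so
    the whole pipeline is testable without access to the original
    administrative data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
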