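Package: dnastraj
Title: Dietary Non-Adherence Score Trajectories and All-Cause Mortality
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the Dietary Non-Adherence Score (DNAS), the Euclidean
    distance between an individual's food-group intake vector and the
    reference intakes of a dietary guideline, and models its change with age
    using latent-class linear mixed trajectory models fitted by EM with
    BIC-based selection of the number of classes. Mortality associations are
    estimated by person-year rates with Poisson confidence intervals,
    sequentially adjusted Cox proportional-hazards models, and
    restricted-cubic-spline Cox dose-response curves. Includes a synthetic
    longitudinal cohort generator with known ground truth, eligibility
    filtering, and an end-to-end pipeline producing reproducible report
    tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    lme4,
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
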