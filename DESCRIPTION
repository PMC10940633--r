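Package: refugiaSDM
Title: Ensemble Habitat Suitability, Climate Refugia and Fishing Risk for
    Deep-Sea Species
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An ensemble species distribution modelling workflow for
    deep-sea habitat-forming species such as the bamboo coral Isidella
    elongata. Prepares presence-absence occurrence data (pseudo-absence
    implantation in presence-only zones, one-record-per-cell aggregation,
    predictor extraction), fits binomial generalized additive models and
    random forests under repeated spatial-block cross-validation, retains
    the best-performing models by AUC quartile, combines their
    threshold-optimised binary maps into an ensemble habitat suitability
    index, quantifies calibration and algorithm uncertainty plus a
    kriging-based model-observation comparison, classifies climate refugia
    under a warmed future scenario, and overlays quartile fishing-effort
    risk classes on observed, suitable and refugial habitat. Includes a
    synthetic seascape generator with a known suitability truth so the
    whole pipeline can be exercised and validated without restricted
    survey data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    mgcv,
    ranger,
    geosphere,
    jsonlite,
    stats,
    utils
Suggests:
    pROC,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
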