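Package: physage
Title: Explainable Personalized Physiological Age from Routine Biomarkers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An explainable machine-learning framework for estimating
    personalized physiological age (PPA) from routine laboratory
    biomarkers. Trains a gradient-boosted tree ensemble on chronological
    age with an age-normalized custom training objective, computes global
    and age-contextualized additive (Shapley) explanations with an
    interventional TreeSHAP implementation, derives the PPA-deviation
    metric and age-specific biomarker thresholds from partial-dependence
    zero crossings, clusters individuals in explanation space with
    Mann-Whitney/Benjamini-Hochberg cluster signatures, reduces models by
    SHAP-importance recursive feature elimination, and validates against
    Klemera-Doubal and homeostatic-dysregulation comparators with
    decile-based Cox proportional-hazards mortality models. Includes a
    synthetic-cohort generator with known per-variable ground truth for
    end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    Rcpp,
    stats,
    survival,
    tools,
    utils,
    xgboost
LinkingTo:
    Rcpp
Suggests:
    arrow,
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
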