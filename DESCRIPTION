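Package: geoseek
Title: Predicting Health Care Utilization from Geotagged Mobile Search Logs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end, seeded pipeline for predicting future medical
    facility visits from geotagged mobile search logs and for evaluating the
    predictions through advertising show-conversion metrics. Includes a
    synthetic search-log simulator with ground truth (facility gazetteer,
    landmark map, toy medical lexicon with ontology structure), geofence
    dwell-time visit detection with cohort inclusion/exclusion filters and
    matched control sampling, 41-search-day longitudinal windowing, daywise and
    aggregate feature engineering (interval reduction score, Fisher/Bonferroni
    token enrichment, information-content search specificity, landmark
    category and location-name features), a model suite (lasso, ridge, elastic
    net, RBF support vector machine, random forest) with cross-validated
    tuning, ROC/AUC and Hand-Till multiclass AUC, leave-one-category-out
    ablation, and offline/online ad evaluation (conversion labeling, local
    show conversion rate curves, bid-coefficient mapping, A/B metrics).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    data.table,
    glmnet,
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
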