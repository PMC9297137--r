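Package: foodsignal
Title: Food-Desert Signals from Geotagged Food-Related Social-Media Text
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A census-tract-level pipeline that turns geotagged short-text
    posts into food-environment features and uses them to screen for and
    predict USDA-style food-desert status. The pipeline filters a geotagged
    corpus to food-related posts, matches multi-word food keywords
    longest-first against a nutrient-annotated lexicon, scores post
    sentiment with a word-polarity lexicon, maps posts to census tracts,
    aggregates tract-level ingestion features, labels tracts by USDA
    low-income/low-access criteria, screens features with covariate-adjusted
    linear regression, and benchmarks feature sets with boosted, logistic,
    and stacked-ensemble classifiers evaluated by AUC. A synthetic-data
    generator emulates every input with a controllable implanted effect
    structure so the whole chain is testable without any external corpus.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    mgcv,
    rpart,
    stats,
    utils,
    xgboost
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
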