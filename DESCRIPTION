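Package: sidefuse
Title: Feature-Fusion Stacked Ensembles for Suicidal-Ideation Detection in Short Posts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects suicidal ideation in short social-media posts by fusing
    three complementary feature families: basic statistical characteristics
    (lexicon-category rates, sentiment-word rates, degree-adverb rates, emoji
    counts, time-of-day bins), suicide-risk-factor rates from a 13-category
    risk dictionary, and word-embedding-cluster keyword rates obtained by
    skip-gram training followed by K-means clustering of candidate keywords.
    Feature matrices are combined under three regimes (direct concatenation,
    select-then-combine, combine-then-select) with extremely-randomized-trees
    feature selection, the best base classifier per feature set is chosen by
    stratified 5-fold cross-validation over a 12-model zoo, and a logistic
    meta-classifier is stacked on out-of-fold base predictions. Ships a
    synthetic corpus generator that emulates an imbalanced microblog dataset
    so the full pipeline is testable without access to restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    withr,
    e1071,
    glmnet,
    rpart,
    class,
    xgboost,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
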