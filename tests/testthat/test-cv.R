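test_that("metrics match hand-computed values from confusion counts", {
  m <- metrics_from_confusion(tp = 74, fp = 14, fn = 26, tn = 886)
  expect_equal(m[["precision"]], 74 / 88, tolerance = 1e-12)
  expect_equal(m[["recall"]], 74 / 100, tolerance = 1e-12)
  expect_equal(m[["f1"]], 2 * (74 / 88) * 0.74 / (74 / 88 + 0.74), tolerance = 1e-12)
  expect_equal(m[["accuracy"]], 0.96, tolerance = 1e-12)

  # always-predict-negative on a 10%-positive set: closed form
  truth <- rep(c(1L, 0L), c(10, 90))
  m0 <- classification_metrics(truth, rep(0L, 100))
  expect_equal(m0[["accuracy"]], 0.9)
  expect_equal(m0[["recall"]], 0)
  expect_equal(m0[["f1"]], 0)
})

test_that("stratified folds depend only on labels, k and seed, and balance classes", {
  y <- rep(c(0L, 1L), c(180, 20))
  f1 <- stratified_folds(y, 5, seed = 3)
  f2 <- stratified_folds(y, 5, seed = 3)
  expect_identical(f1, f2)
  expect_false(identical(f1, stratified_folds(y, 5, seed = 4)))
  # every fold holds exactly 1/5 of each class
  for (f in 1:5) {
    expect_equal(sum(y[f1 == f] == 1), 4)
    expect_equal(sum(y[f1 == f] == 0), 36)
  }
  expect_error(stratified_folds(rep(c(0L, 1L), c(98, 2)), 5), "fewer than k")
})

test_that("a decision tree reaches perfect accuracy on separable data", {
  withr::with_seed(5, {
    y <- rep(c(0L, 1L), each = 40)
    x <- matrix(y * 2 + runif(80, -0.5, 0.5), ncol = 1,
                dimnames = list(NULL, "f"))
  })
  fb <- feature_block(x, "BSC", sprintf("p%02d", 1:80))
  res <- evaluate_cv(fb, y, "DT-g", seed = 2)
  expect_equal(res$pooled[["accuracy"]], 1.0)
  # rerun reproduces metrics exactly
  res2 <- evaluate_cv(fb, y, "DT-g", seed = 2)
  expect_identical(res$pooled, res2$pooled)
})

test_that("every zoo model fits, predicts, and returns metrics in range", {
  cfg <- small_config(seed = 17, n_pos = 40, n_neg = 160)
  lex <- make_fixture_lexicons(cfg)
  corp <- generate_corpus(cfg, lex)
  fb <- rfs_block(corp, lex$risk)
  y <- corpus_labels(corp)
  for (id in model_zoo()) {
    res <- evaluate_cv(fb, y, id, seed = 1)
    expect_true(all(res$pooled >= 0 & res$pooled <= 1), label = id)
    expect_equal(length(res$oof), length(y))
  }
})

test_that("probability predictions are valid probabilities for stacking bases", {
  withr::with_seed(6, {
    y <- rep(c(0L, 1L), each = 50)
    x <- matrix(rnorm(200) + y, ncol = 2, dimnames = list(NULL, c("u", "v")))
  })
  for (id in c("SVM-l", "NB", "KNN", "Log-l2", "DT-g", "ET-g")) {
    fit <- fit_model(id, x, y, seed = 1, probability = TRUE)
    p <- predict_model(fit, x, type = "prob")
    expect_true(all(p >= 0 & p <= 1), label = id)
  }
})

test_that("select_best picks by accuracy with F1 and zoo-order tie-breaks", {
  cfg <- small_config(seed = 19, n_pos = 30, n_neg = 120)
  lex <- make_fixture_lexicons(cfg)
  corp <- generate_corpus(cfg, lex)
  fb <- rfs_block(corp, lex$risk)
  y <- corpus_labels(corp)

  one <- select_best(fb, y, zoo = "NB", seed = 1)
  expect_equal(one$best, "NB")

  sb <- select_best(fb, y, zoo = c("NB", "DT-g", "ET-g"), seed = 1)
  lb <- sb$leaderboard
  best_acc <- max(lb$accuracy)
  expect_equal(lb$accuracy[lb$model == sb$best], best_acc)
  # among accuracy ties the winner has the top F1, and zoo order breaks the rest
  tied <- lb[lb$accuracy == best_acc, ]
  expect_equal(sb$best, tied$model[order(-tied$f1)][1])

  # exact tie (duplicated zoo entry): first in zoo order wins
  dup <- select_best(fb, y, zoo = c("DT-g", "DT-g"), seed = 1)
  expect_equal(dup$best, "DT-g")
})
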