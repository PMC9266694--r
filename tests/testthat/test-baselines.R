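test_that("all nine baselines run under shared folds; the dummy hits the prevalence", {
  cfg <- small_config(seed = 29, n_pos = 45, n_neg = 255)
  lex <- make_fixture_lexicons(cfg)
  corp <- generate_corpus(cfg, lex)
  fb <- cbind_blocks(bsc_block(corp, lex), rfs_block(corp, lex$risk))
  y <- corpus_labels(corp)

  res <- run_baselines(fb, y, seed = 1)
  expect_length(res, 9)
  expect_setequal(names(res), baseline_ids())
  for (r in res) {
    expect_true(all(r$pooled >= 0 & r$pooled <= 1), label = r$model)
  }
  # paired comparison: identical fold assignment across baselines
  folds <- lapply(res, `[[`, "fold")
  for (f in folds[-1]) expect_identical(f, folds[[1]])
  # the majority-class dummy scores exactly the negative prevalence
  expect_equal(res$DummyMajority$pooled[["accuracy"]], mean(y == 0))
  expect_equal(res$DummyMajority$pooled[["f1"]], 0)
})

fake_result <- function(id, acc = 0.5) {
  structure(list(model = id,
                 pooled = c(accuracy = acc, f1 = 0.4, precision = 0.3,
                            recall = 0.2),
                 per_fold = NULL, oof = NULL, fold = 1:5, seed = 1),
            class = "cv_result")
}

test_that("report writes four percentage-formatted tables and a stable config hash", {
  results <- list(
    single = list(BSC = fake_result("ET-g", 0.7449)),
    multi = list(`BSC + RFS` = fake_result("Log-l2", 0.7806)),
    fusion = list(`(BSC + RFS)-fs / WEC-fs` = fake_result("fusion", 0.8061)),
    baselines = list(Stacking = fake_result("Stacking", 0.7977)),
    optimum = c(BSC = "ET-g", `BSC + RFS` = "Log-l2")
  )
  out1 <- withr::local_tempdir()
  report(results, out1, config = list(seed = 1))
  files <- list.files(out1)
  expect_setequal(files, c("single_features.csv", "multi_features.csv",
                           "fusion_feature_sets.csv", "ensemble_baselines.csv",
                           "report.md", "run_metadata.json"))
  single <- utils::read.csv(file.path(out1, "single_features.csv"),
                            check.names = FALSE)
  expect_equal(single$Accuracy, "74.49%")
  expect_equal(single$`Optimum Classifier`, "ET-g")

  # identical config -> identical hash; different config -> different hash
  out2 <- withr::local_tempdir()
  report(results, out2, config = list(seed = 1))
  meta1 <- jsonlite::fromJSON(file.path(out1, "run_metadata.json"))
  meta2 <- jsonlite::fromJSON(file.path(out2, "run_metadata.json"))
  expect_equal(meta1$config_hash, meta2$config_hash)
  out3 <- withr::local_tempdir()
  report(results, out3, config = list(seed = 2))
  meta3 <- jsonlite::fromJSON(file.path(out3, "run_metadata.json"))
  expect_false(meta1$config_hash == meta3$config_hash)
})

test_that("forest importances are normalized and bootstrap/best-split modes fit", {
  withr::with_seed(7, {
    y <- rep(c(0L, 1L), each = 60)
    x <- matrix(rnorm(240) + 0.8 * y, ncol = 2,
                dimnames = list(NULL, c("a", "b")))
  })
  for (crit in c("gini", "entropy")) {
    for (split in c("random", "best")) {
      f <- sf_forest(x, y, n_trees = 30, criterion = crit, split = split,
                     bootstrap = (split == "best"), seed = 5)
      expect_equal(sum(f$importance), 1, tolerance = 1e-9)
      p <- predict(f, x, type = "prob")
      expect_true(all(p >= 0 & p <= 1))
      expect_gt(classification_metrics(y, as.integer(p >= 0.5))[["accuracy"]], 0.7)
    }
  }
  # determinism
  f1 <- sf_forest(x, y, n_trees = 20, seed = 9)
  f2 <- sf_forest(x, y, n_trees = 20, seed = 9)
  expect_identical(predict(f1, x), predict(f2, x))
})
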