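small_blocks <- function(seed = 23, n_pos = 40, n_neg = 260) {
  cfg <- small_config(seed = seed, n_pos = n_pos, n_neg = n_neg)
  lex <- make_fixture_lexicons(cfg)
  corp <- generate_corpus(cfg, lex)
  fam <- build_family_blocks(corp, lex, wec_k = 5, wec_m = 10, wec_dim = 30,
                             wec_epochs = 3, seed = seed)
  list(blocks = fam$blocks, y = corpus_labels(corp))
}

test_that("ensemble specs enforce coverage and set-count invariants", {
  r <- function(s) parse_recipe(s)
  expect_error(ensemble_spec(list(r("BSC+RFS+WEC"))), "at least 2")
  expect_error(ensemble_spec(list(r("BSC"), r("RFS"))), "WEC")
  spec <- ensemble_spec(list(r("(BSC+RFS)-fs"), r("WEC-fs")))
  expect_equal(spec$label, "(BSC + RFS)-fs / WEC-fs")
  expect_error(ensemble_spec(list(r("BSC"), r("RFS"), r("WEC")),
                             base_models = c("NB", "NB")), "one id per")
})

test_that("the 11 reference configurations are enumerated with full coverage", {
  specs <- enumerate_paper_feature_sets()
  expect_length(specs, 11)
  labels <- vapply(specs, `[[`, "", "label")
  expect_true("(BSC + RFS)-fs / WEC-fs" %in% labels) # headline configuration
  expect_equal(anyDuplicated(labels), 0)
  for (spec in specs) {
    covered <- unique(unlist(lapply(spec$feature_sets, `[[`, "blocks")))
    expect_setequal(covered, c("BSC", "RFS", "WEC"))
  }
})

test_that("out-of-fold meta-features are probabilities with one column per feature set", {
  d <- small_blocks()
  sel <- selection_config(n_trees = 100, seed = 23)
  spec <- ensemble_spec(list(parse_recipe("(BSC+RFS)-fs", sel),
                             parse_recipe("WEC-fs", sel)),
                        base_models = c("Log-l2", "NB"), seed = 23)
  meta <- build_meta_features(spec, d$blocks, d$y)
  expect_equal(dim(meta), c(length(d$y), 2))
  expect_true(all(meta >= 0 & meta <= 1))
  expect_equal(colnames(meta), c("(BSC + RFS)-fs", "WEC-fs"))
  # deterministic under the same spec seed
  meta2 <- build_meta_features(spec, d$blocks, d$y)
  expect_identical(meta, meta2)
  # unset base models are rejected
  spec0 <- ensemble_spec(list(parse_recipe("BSC+RFS"), parse_recipe("WEC")))
  expect_error(build_meta_features(spec0, d$blocks, d$y), "base models")
})

test_that("a fitted fusion ensemble predicts labels and probabilities in range", {
  d <- small_blocks()
  sel <- selection_config(n_trees = 100, seed = 23)
  spec <- ensemble_spec(list(parse_recipe("(BSC+RFS)-fs", sel),
                             parse_recipe("WEC-fs", sel)),
                        base_models = c("Log-l2", "NB"), seed = 23)
  fit <- fit_fusion(spec, d$blocks, d$y)
  cls <- predict(fit, d$blocks, type = "class")
  prb <- predict(fit, d$blocks, type = "prob")
  expect_true(all(cls %in% c(0L, 1L)))
  expect_true(all(prb >= 0 & prb <= 1))
  expect_equal(length(cls), length(d$y))
})

test_that("with identical base models and features, fusion agrees with the base classifier", {
  d <- small_blocks()
  spec <- ensemble_spec(list(parse_recipe("BSC+RFS+WEC"),
                             parse_recipe("BSC+RFS+WEC")),
                        base_models = c("Log-l2", "Log-l2"), seed = 23)
  fit <- fit_fusion(spec, d$blocks, d$y)
  fusion_cls <- predict(fit, d$blocks, type = "class")
  base_cls <- predict_model(fit$base_fits[[1]]$fit,
                            cbind_blocks(d$blocks)$matrix, type = "class")
  expect_gt(mean(fusion_cls == base_cls), 0.98)
})

test_that("nested fusion evaluation returns pooled out-of-sample metrics", {
  d <- small_blocks()
  sel <- selection_config(n_trees = 50, seed = 23)
  spec <- ensemble_spec(list(parse_recipe("(BSC+RFS)-fs", sel),
                             parse_recipe("WEC-fs", sel)),
                        base_models = c("Log-l2", "NB"), seed = 23)
  res <- evaluate_fusion_cv(spec, d$blocks, d$y, seed = 23)
  expect_s3_class(res, "cv_result")
  expect_true(all(res$pooled >= 0 & res$pooled <= 1))
  expect_false(anyNA(res$oof))
})
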