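# shared construction: one perfectly separating column among noise
sep_block <- function(n = 200, p_noise = 50, seed = 8) {
  withr::with_seed(seed, {
    y <- rep(c(0L, 1L), each = n / 2)
    x <- matrix(runif(n * p_noise), n, p_noise)
    sep <- y + runif(n, -0.2, 0.2)
    m <- cbind(sep = sep, x)
    colnames(m) <- c("sep", sprintf("noise%02d", seq_len(p_noise)))
    list(block = feature_block(m, "BSC", sprintf("p%03d", seq_len(n))), y = y)
  })
}

test_that("a perfectly separating column dominates the importance ranking", {
  d <- sep_block()
  sel <- fit_importance_selector(d$block, d$y,
                                 selection_config(n_trees = 100, seed = 1))
  expect_equal(names(sort(sel$importances, decreasing = TRUE))[1], "sep")
  expect_equal(sum(sel$importances), 1, tolerance = 1e-9)
  # stump oracle: its single-split impurity decrease dwarfs every noise column
  gains <- apply(d$block$matrix, 2, stump_gain, y = d$y)
  expect_equal(names(which.max(gains)), "sep")
  expect_gt(gains["sep"], 10 * max(gains[-1]))
})

test_that("keep rules behave: top-k identity, non-increasing order, idempotence", {
  d <- sep_block(n = 120, p_noise = 10)
  cfg_all <- selection_config(n_trees = 50, top_k = 11, seed = 2)
  sel_all <- fit_importance_selector(d$block, d$y, cfg_all)
  expect_setequal(sel_all$kept, colnames(d$block$matrix)) # k = n_features

  cfg <- selection_config(n_trees = 50, fraction = 0.6, seed = 2)
  sel <- fit_importance_selector(d$block, d$y, cfg)
  imp_kept <- sel$importances[sel$kept]
  expect_true(all(diff(imp_kept) <= 1e-12)) # ranked prefix

  reduced <- apply_selector(sel, d$block)
  sel2 <- fit_importance_selector(reduced, d$y, cfg)
  # idempotence: reselecting an already-selected block keeps everything
  reduced2 <- apply_selector(sel2, reduced)
  expect_setequal(colnames(reduced2$matrix), colnames(reduced$matrix))

  expect_error(fit_importance_selector(d$block, rep(1L, 120), cfg), "single class")
  expect_error(selection_config(fraction = 1.5), "fraction")
})

test_that("recipe strings parse into the right blocks and modes", {
  r1 <- parse_recipe("BSC+RFS")
  expect_equal(r1$mode, "direct")
  expect_setequal(r1$blocks, c("BSC", "RFS"))
  r2 <- parse_recipe("(BSC-fs)+(WEC-fs)")
  expect_equal(r2$mode, "select-then-combine")
  r3 <- parse_recipe("(BSC + RFS + WEC)-fs")
  expect_equal(r3$mode, "combine-then-select")
  expect_length(r3$blocks, 3)
  r4 <- parse_recipe("WEC-fs")
  expect_equal(r4$mode, "select-then-combine")
  expect_equal(r4$label, "WEC-fs")
  expect_error(parse_recipe("BSC+XYZ"), "unknown")
  expect_error(parse_recipe("BSC+BSC"), "repeated")
})

test_that("the three combination regimes produce the documented widths and tags", {
  d <- xor_blocks()
  direct <- apply_recipe(combination_recipe(c("BSC", "RFS"), "direct"),
                         d$blocks)
  expect_equal(ncol(direct$matrix), 4)
  expect_equal(direct$block, c("BSC", "BSC", "RFS", "RFS"))

  cfg <- selection_config(n_trees = 100, top_k = 1, seed = 3)
  stc <- apply_recipe(combination_recipe(c("BSC", "RFS"),
                                         "select-then-combine", cfg),
                      d$blocks, d$y)
  expect_equal(ncol(stc$matrix), 2) # sum of per-block min(k, width)
  expect_length(unique(stc$block), 2)
})

test_that("combine-then-select finds the jointly informative pair that per-block selection misses", {
  d <- xor_blocks()
  # per block, the xor half carries no marginal signal: its stump gain is
  # negligible next to the weak marginal column's
  expect_lt(stump_gain(d$blocks$BSC$matrix[, "x1"], d$y),
            stump_gain(d$blocks$BSC$matrix[, "weak_a"], d$y) / 2)

  stc <- apply_recipe(combination_recipe(c("BSC", "RFS"), "select-then-combine",
                                         selection_config(n_trees = 200, top_k = 1, seed = 4)),
                      d$blocks, d$y)
  cts <- apply_recipe(combination_recipe(c("BSC", "RFS"), "combine-then-select",
                                         selection_config(n_trees = 200, top_k = 2, seed = 4)),
                      d$blocks, d$y)
  expect_setequal(colnames(stc$matrix), c("weak_a", "weak_b"))
  expect_setequal(colnames(cts$matrix), c("x1", "x2"))
  expect_false(setequal(colnames(stc$matrix), colnames(cts$matrix)))
})
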