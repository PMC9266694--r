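lex <- tiny_lexicons()
corp <- tiny_corpus()

test_that("category rates match hand counts and handle multi-membership", {
  fb <- liwc_category_features(corp, lex$liwc)
  # post a: 10 tokens, "sad"+"cry" in sad, "think" in cog
  expect_equal(unname(fb$matrix[1, "liwc.sad"]), 0.2)
  expect_equal(unname(fb$matrix[1, "liwc.cog"]), 0.1)
  # post d: no lexicon tokens -> zero row
  expect_equal(unname(fb$matrix[4, ]), rep(0, 3))
  expect_true(all(fb$block == "BSC"))

  # a token in two categories contributes to both
  twice <- si_lexicon("l2", list(a = "dual", b = c("dual", "other")),
                      "category-count")
  df <- as.data.frame(corp)[1, ]
  df$tokens <- list(c("dual", "x"))
  df$pos <- list(c("n", "n"))
  one <- si_corpus(df)
  fb2 <- liwc_category_features(one, twice)
  expect_equal(unname(fb2$matrix[1, ]), c(0.5, 0.5))
})

test_that("polarity rates hit their hand-computed values and bounds", {
  fb <- polarity_features(corp, lex$polarity)
  # post b: bad, sad, awful among 12 tokens
  expect_equal(unname(fb$matrix[2, "polarity.negative"]), 3 / 12)
  # post d: no polarity words
  expect_equal(unname(fb$matrix[4, ]), c(0, 0))
  # all-negative post reaches the upper bound 1
  df <- as.data.frame(corp)[1, ]
  df$tokens <- list(c("bad", "awful", "sad"))
  df$pos <- list(rep("a", 3))
  fb2 <- polarity_features(si_corpus(df), lex$polarity)
  expect_equal(unname(fb2$matrix[1, "polarity.negative"]), 1.0)
  expect_true(all(fb$matrix >= 0 & fb$matrix <= 1))
})

test_that("degree-adverb block always has the 4 level columns", {
  fb <- degree_adverb_features(corp, lex$degree)
  expect_equal(ncol(fb$matrix), 4)
  expect_equal(unname(fb$matrix[3, "degree.level1"]), 0.2) # "slightly" among 5 tokens
  expect_equal(unname(fb$matrix[1, ]), rep(0, 4))
})

test_that("emoji features count risk emojis and total separately", {
  fb <- emoji_features(corp, lex$emoji)
  expect_equal(unname(fb$matrix[1, "emoji.Knife"]), 2)
  expect_equal(unname(fb$matrix[1, "emoji.total"]), 2)
  # unlisted emoji counts only toward the total
  expect_equal(unname(fb$matrix[3, "emoji.total"]), 1)
  expect_equal(sum(fb$matrix[3, c("emoji.Knife", "emoji.Drugs")]), 0)
  expect_equal(unname(fb$matrix[2, ]), rep(0, 3))
})

test_that("time bins are one-hot over 8 half-open 3h periods anchored at midnight", {
  fb <- time_bin_features(corp)
  expect_equal(ncol(fb$matrix), 8)
  expect_true(all(rowSums(fb$matrix) == 1))
  expect_equal(unname(fb$matrix[1, "time.bin0"]), 1) # 00:00
  expect_equal(unname(fb$matrix[2, "time.bin0"]), 1) # 02:59
  expect_equal(unname(fb$matrix[3, "time.bin1"]), 1) # 03:00
  expect_equal(unname(fb$matrix[4, "time.bin7"]), 1) # 23:59
})

test_that("bsc block concatenates the five sub-blocks with BSC tags and preserved row order", {
  fb <- bsc_block(corp, lex)
  expected_width <- 3 + 2 + 4 + (2 + 1) + 8
  expect_equal(ncol(fb$matrix), expected_width)
  expect_true(all(fb$block == "BSC"))
  expect_equal(fb$row_ids, corp$id)

  # permuting the corpus permutes feature rows identically
  perm <- c(3, 1, 4, 2)
  corp_p <- si_corpus(as.data.frame(corp)[perm, ], provenance = "perm")
  fb_p <- bsc_block(corp_p, lex)
  expect_equal(unname(fb_p$matrix), unname(fb$matrix[perm, ]))
})
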