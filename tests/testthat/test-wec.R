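# --- skip-gram embeddings -------------------------------------------------

# 50 sentences over 5 disjoint topics: words of one topic only ever co-occur
# with each other, so their shared contexts must pull their vectors together
toy_sentences_corpus <- function(seed = 42) {
  withr::with_seed(seed, {
    topics <- lapply(1:5, function(t) sprintf("t%d_%s", t, letters[1:4]))
    df <- data.frame(id = sprintf("s%02d", 1:50), text = "",
                     stringsAsFactors = FALSE)
    df$tokens <- lapply(1:50, function(i) {
      sample(topics[[(i - 1) %% 5 + 1]], 8, replace = TRUE)
    })
    df$pos <- lapply(df$tokens, function(tk) rep("n", length(tk)))
    df$hour <- rep(12L, 50); df$minute <- rep(0L, 50)
    df$emojis <- rep(list(character(0)), 50)
    df$label <- rep(0L, 50)
    si_corpus(df)
  })
}

test_that("words sharing all their contexts embed closer than the median pair", {
  corp <- toy_sentences_corpus()
  emb <- train_skipgram(corp, dim = 24, window = 3, epochs = 20,
                        min_count = 2, seed = 4)
  v <- emb$vectors
  v <- v / sqrt(rowSums(v^2))
  sims <- v %*% t(v)
  all_pairs <- sims[upper.tri(sims)]
  med <- stats::median(all_pairs)
  # same-topic pairs (exclusive co-occurrence) sit above the global median
  expect_gt(sims["t1_a", "t1_b"], med)
  expect_gt(sims["t3_a", "t3_c"], med)
  # and above the typical cross-topic pair
  expect_gt(sims["t1_a", "t1_b"], sims["t1_a", "t2_a"])
})

test_that("skip-gram training respects min_count and is seed-deterministic", {
  corp <- toy_sentences_corpus()
  df <- as.data.frame(corp)
  df$tokens[[1]] <- c(df$tokens[[1]], "hapax") # occurs once
  df$pos[[1]] <- rep("n", length(df$tokens[[1]]))
  corp2 <- si_corpus(df)
  emb <- train_skipgram(corp2, dim = 8, epochs = 2, min_count = 2, seed = 1)
  expect_false("hapax" %in% emb$vocabulary)

  emb_a <- train_skipgram(corp, dim = 8, epochs = 2, seed = 5)
  emb_b <- train_skipgram(corp, dim = 8, epochs = 2, seed = 5)
  expect_identical(emb_a$vectors, emb_b$vectors)
  emb_c <- train_skipgram(corp, dim = 8, epochs = 2, seed = 6)
  expect_false(identical(emb_a$vectors, emb_c$vectors))
})

test_that("embeddings round-trip through word2vec text format", {
  corp <- toy_sentences_corpus()
  emb <- train_skipgram(corp, dim = 6, epochs = 1, seed = 2)
  path <- withr::local_tempfile(fileext = ".txt")
  write_embeddings(emb, path)
  back <- read_embeddings(path)
  expect_equal(back$vocabulary, emb$vocabulary)
  expect_equal(back$vectors, emb$vectors, tolerance = 1e-6)
})

# --- candidate extraction -------------------------------------------------

test_that("candidate extraction filters by POS and embedding vocabulary", {
  df <- data.frame(id = c("a", "b"), text = "", stringsAsFactors = FALSE)
  df$tokens <- list(c("run", "the", "run", "knife"), c("of", "to"))
  df$pos <- list(c("v", "u", "v", "n"), c("u", "u"))
  df$hour <- c(1L, 1L); df$minute <- c(0L, 0L)
  df$emojis <- list(character(0), character(0))
  df$label <- c(0L, 0L)
  corp <- si_corpus(df)

  expect_equal(extract_candidates(corp), c("run", "knife")) # dedup, order kept
  # all function words -> empty
  expect_length(extract_candidates(corp, pos_keep = "x"), 0)
  # candidate missing from the embedding vocabulary is dropped
  emb <- fake_embeddings(matrix(1:4, 2, 2, dimnames = list(c("run", "x"), NULL)))
  expect_equal(extract_candidates(corp, embeddings = emb), "run")
})

# --- k-means --------------------------------------------------------------

test_that("kmeans recovers the obvious 1-D two-cluster split", {
  x <- matrix(c(0, 0.1, 10, 10.1), ncol = 1,
              dimnames = list(c("a", "b", "c", "d"), NULL))
  emb <- fake_embeddings(x)
  cl <- kmeans_cluster(c("a", "b", "c", "d"), emb, k = 2, seed = 1)
  expect_equal(cl$assignments[["a"]], cl$assignments[["b"]])
  expect_equal(cl$assignments[["c"]], cl$assignments[["d"]])
  expect_false(cl$assignments[["a"]] == cl$assignments[["c"]])
  expect_setequal(round(cl$centroids[, 1], 6), c(0.05, 10.05))
  # matches the brute-force optimum
  expect_equal(cl$wss, brute_force_wss(x, 2)$wss, tolerance = 1e-9)
})

test_that("k equal to n gives singleton clusters with zero distances; k > n errors", {
  x <- matrix(rnorm(6), ncol = 2, dimnames = list(c("a", "b", "c"), NULL))
  emb <- fake_embeddings(x)
  cl <- kmeans_cluster(c("a", "b", "c"), emb, k = 3, seed = 2)
  expect_equal(sort(unname(cl$assignments)), 1:3)
  expect_lt(max(cl$distances), 1e-6) # zero up to fp noise
  expect_error(kmeans_cluster(c("a", "b", "c"), emb, k = 4, seed = 1), "exceeds")
})

test_that("duplicated points reach the same centroids as the deduplicated weighted problem", {
  base <- matrix(c(0, 0, 1, 1, 5, 5), ncol = 2, byrow = TRUE)
  x <- rbind(base, base) # every point duplicated = weight 2
  rownames(x) <- sprintf("p%d", 1:6)
  emb <- fake_embeddings(x)
  cl <- kmeans_cluster(rownames(x), emb, k = 2, seed = 3)
  # the weighted optimum has the same centroids as the unweighted one here
  oracle <- brute_force_wss(x, 2)
  expect_equal(cl$wss, oracle$wss, tolerance = 1e-9)
})

test_that("the within-cluster objective never increases across iterations", {
  withr::with_seed(99, {
    for (rep in 1:10) {
      x <- matrix(rnorm(30), ncol = 2)
      rownames(x) <- sprintf("p%02d", 1:15)
      cl <- kmeans_cluster(rownames(x), fake_embeddings(x), k = 3, seed = rep)
      expect_true(all(diff(cl$wss_trace) <= 1e-9))
      expect_true(all(cl$distances >= 0))
    }
  })
})

# --- keyword selection and featurization ----------------------------------

fixed_clustering <- function() {
  structure(list(
    candidates = c("a", "b", "c", "d", "e"),
    assignments = c(a = 1L, b = 1L, c = 2L, d = 2L, e = 2L),
    centroids = matrix(0, 2, 2),
    distances = c(a = 0.1, b = 0.3, c = 0.2, d = 0.2, e = 0.5),
    wss = NA_real_, wss_trace = numeric(0), k = 2L, iterations = 1L),
    class = "keyword_clustering")
}

test_that("keyword selection ranks by distance with lexicographic ties", {
  cl <- fixed_clustering()
  expect_equal(select_keywords(cl, 1), c("a", "c")) # nearest per cluster; c<d tie
  expect_equal(select_keywords(cl, 2), c("a", "b", "c", "d"))
  expect_equal(select_keywords(cl, 10), c("a", "b", "c", "d", "e")) # whole clusters
})

test_that("wec block yields keyword rates plus conserved cluster aggregates", {
  cl <- fixed_clustering()
  kw <- select_keywords(cl, 2)
  df <- data.frame(id = c("p1", "p2"), text = "", stringsAsFactors = FALSE)
  df$tokens <- list(c("a", "c", "c", "z"), c("z", "z"))
  df$pos <- list(rep("n", 4), rep("n", 2))
  df$hour <- c(1L, 1L); df$minute <- c(0L, 0L)
  df$emojis <- list(character(0), character(0))
  df$label <- c(1L, 0L)
  corp <- si_corpus(df)

  fb <- wec_block(corp, kw, cl)
  expect_equal(ncol(fb$matrix), length(kw) + cl$k)
  expect_true(all(fb$block == "WEC"))
  expect_equal(unname(fb$matrix[1, "wec.kw.a"]), 0.25)
  expect_equal(unname(fb$matrix[1, "wec.kw.c"]), 0.5)
  expect_equal(unname(fb$matrix[2, ]), rep(0, ncol(fb$matrix))) # no keywords
  # cluster aggregate = sum of its keyword columns
  expect_equal(unname(fb$matrix[, "wec.cluster01"]),
               unname(rowSums(fb$matrix[, c("wec.kw.a", "wec.kw.b")])))
  expect_equal(unname(fb$matrix[, "wec.cluster02"]),
               unname(rowSums(fb$matrix[, c("wec.kw.c", "wec.kw.d")])))
})

test_that("selected keywords overlap the planted risk vocabulary more as enrichment grows", {
  jaccards <- vapply(c(1, 8), function(mult) {
    cfg <- small_config(seed = 31, n_pos = 250, n_neg = 250,
                        enrichment = c("risk-dictionary:*" = mult))
    lex <- make_fixture_lexicons(cfg)
    corp <- generate_corpus(cfg, lex)
    wec <- wec_pipeline(corp, k = 6, m_per_cluster = 15, dim = 30,
                        epochs = 3, seed = 31)
    riskw <- unlist(lex$risk$categories)
    kw <- wec$keywords
    length(intersect(kw, riskw)) / length(union(kw, riskw))
  }, 0)
  expect_gt(jaccards[2], jaccards[1])
})
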