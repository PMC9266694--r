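# Shared fixtures: a tiny hand-built corpus/lexicon set with known counts,
# a small synthetic configuration, and the brute-force k-means oracle.

tiny_lexicons <- function() {
  list(
    liwc = si_lexicon("liwc", list(
      sad = c("sad", "cry", "tear"),
      cog = c("think", "know"),
      social = c("friend", "mother")
    ), "category-count"),
    polarity = si_lexicon("pol", list(
      positive = c("good", "happy", "nice"),
      negative = c("bad", "sad", "awful")
    ), "polarity"),
    degree = si_lexicon("deg", list(
      level1 = "slightly", level2 = "quite", level3 = "very", level4 = "utterly"
    ), "degree-adverb"),
    emoji = si_lexicon("emo", list(
      risk = c("Knife", "Drugs"),
      common = c("Smile", "Heart")
    ), "emoji"),
    risk = si_lexicon("risk", stats::setNames(
      lapply(1:13, function(j) sprintf("rk%02d_%d", j, 1:2)),
      sprintf("cat%02d", 1:13)), "risk-dictionary")
  )
}

# posts with hand-countable feature values
tiny_corpus <- function() {
  df <- data.frame(id = c("a", "b", "c", "d"),
                   text = "", stringsAsFactors = FALSE)
  df$tokens <- list(
    c("sad", "cry", "think", "good", "filler", "filler", "filler", "filler", "filler", "filler"),
    c("bad", "sad", "awful", "x1", "x2", "x3", "x4", "x5", "x6", "x7", "x8", "x9"),
    c("slightly", "friend", "know", "w", "w"),
    c("filler", "filler")
  )
  df$pos <- list(rep("n", 10), rep("n", 12), c("d", "n", "v", "u", "u"), c("u", "u"))
  df$hour <- c(0L, 2L, 3L, 23L)
  df$minute <- c(0L, 59L, 0L, 59L)
  df$emojis <- list(c("Knife", "Knife"), character(0), c("Party"), c("Smile"))
  df$label <- c(1L, 1L, 0L, 0L)
  si_corpus(df, provenance = "fixture")
}

small_config <- function(seed = 7L, n_pos = 60L, n_neg = 540L, ...) {
  generator_config(n_pos = n_pos, n_neg = n_neg, seed = seed, ...)
}

# embedding table holding arbitrary fixed vectors, for clustering tests
fake_embeddings <- function(vectors) {
  structure(list(vocabulary = rownames(vectors), vectors = vectors,
                 config = list(dim = ncol(vectors), window = NA, epochs = NA,
                               min_count = NA, negative = NA, alpha = NA,
                               seed = NA)),
            class = "embedding_table")
}

# exhaustive k-means oracle: minimal within-cluster sum of squares over all
# assignments of n points to k labels (empty clusters allowed, matching the
# k-means objective with <= k effective clusters)
brute_force_wss <- function(x, k) {
  n <- nrow(x)
  best <- Inf
  assign_best <- NULL
  grid <- rep(list(seq_len(k)), n)
  all_assign <- as.matrix(expand.grid(grid))
  for (r in seq_len(nrow(all_assign))) {
    a <- all_assign[r, ]
    wss <- 0
    for (j in unique(a)) {
      pts <- x[a == j, , drop = FALSE]
      ctr <- colMeans(pts)
      wss <- wss + sum(sweep(pts, 2, ctr)^2)
    }
    if (wss < best - 1e-12) { best <- wss; assign_best <- a }
  }
  list(wss = best, assignment = assign_best)
}

# single-split decision-stump oracle: best gini impurity decrease achievable
# by thresholding one feature
stump_gain <- function(x_col, y) {
  n <- length(y)
  gini <- function(idx) {
    if (length(idx) == 0) return(0)
    p <- mean(y[idx])
    1 - p^2 - (1 - p)^2
  }
  parent <- gini(seq_len(n))
  cuts <- sort(unique(x_col))
  if (length(cuts) < 2) return(0)
  thr <- (head(cuts, -1) + cuts[-1]) / 2
  max(vapply(thr, function(t) {
    l <- which(x_col <= t); r <- which(x_col > t)
    parent - length(l) / n * gini(l) - length(r) / n * gini(r)
  }, 0))
}

# XOR construction: each block holds one half of a jointly informative pair
# plus a weakly informative marginal column; only joint selection can find
# the pair
xor_blocks <- function(n = 400, seed = 10) {
  withr::with_seed(seed, {
    x1 <- rbinom(n, 1, 0.5)
    x2 <- rbinom(n, 1, 0.5)
    y <- as.integer(xor(x1, x2))
    flip <- function() ifelse(runif(n) < 0.45, 1L - y, y)
    a <- cbind(x1 = x1, weak_a = flip() + runif(n, 0, 0.01))
    b <- cbind(x2 = x2, weak_b = flip() + runif(n, 0, 0.01))
    list(blocks = list(BSC = feature_block(a, "BSC", sprintf("p%03d", 1:n)),
                       RFS = feature_block(b, "RFS", sprintf("p%03d", 1:n))),
         y = y)
  })
}

# rank-based AUC of scores against binary truth
simple_auc <- function(truth, score) {
  r <- rank(score)
  n1 <- sum(truth == 1); n0 <- sum(truth == 0)
  (sum(r[truth == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
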