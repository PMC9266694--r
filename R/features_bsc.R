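# Basic statistical characteristics: lexicon-category rates, sentiment-word
# rates, degree-adverb rates, emoji counts, and time-of-day bins.

# count, per post, how many tokens fall in each category of a lexicon;
# returns n_posts x n_categories count matrix
category_counts <- function(corpus, categories) {
  cat_names <- names(categories)
  out <- matrix(0, nrow(corpus), length(cat_names),
                dimnames = list(NULL, cat_names))
  for (j in seq_along(cat_names)) {
    pool <- categories[[j]]
    out[, j] <- vapply(corpus$tokens, function(tk) sum(tk %in% pool), 0)
  }
  out
}

rate_block <- function(corpus, categories, prefix, tag) {
  counts <- category_counts(corpus, categories)
  lens <- lengths(corpus$tokens)
  rates <- counts / lens
  colnames(rates) <- paste0(prefix, colnames(rates))
  feature_block(rates, tag, corpus$id)
}

#' LIWC-style category rate features
#'
#' One column per lexicon category, holding the share of the post's tokens
#' that fall in that category. A token belonging to several categories
#' contributes to every one of them (the usual category-lexicon convention).
#'
#' @param corpus an [si_corpus()]
#' @param lexicon a `category-count` [si_lexicon()]
#' @return a `feature_block` tagged `BSC`
#' @export
liwc_category_features <- function(corpus, lexicon) {
  if (nrow(corpus) == 0) stop("empty corpus")
  stopifnot(lexicon$kind == "category-count")
  rate_block(corpus, lexicon$categories, "liwc.", "BSC")
}

#' Positive/negative sentiment-word rate features
#' @param corpus an [si_corpus()]
#' @param polarity a polarity [si_lexicon()]
#' @return a 2-column `feature_block` tagged `BSC`
#' @export
polarity_features <- function(corpus, polarity) {
  if (nrow(corpus) == 0) stop("empty corpus")
  stopifnot(polarity$kind == "polarity")
  rate_block(corpus, polarity$categories[c("positive", "negative")], "polarity.", "BSC")
}

#' Degree-adverb rate features (4 intensity levels)
#' @param corpus an [si_corpus()]
#' @param degrees a degree-adverb [si_lexicon()]
#' @return a 4-column `feature_block` tagged `BSC`
#' @export
degree_adverb_features <- function(corpus, degrees) {
  if (nrow(corpus) == 0) stop("empty corpus")
  stopifnot(degrees$kind == "degree-adverb")
  rate_block(corpus, degrees$categories, "degree.", "BSC")
}

#' Emoji count features
#'
#' One absolute-count column per listed risk emoji, plus a total emoji count.
#' Emojis not listed as risk emojis contribute only to the total column.
#' Counts rather than rates: emoji use is a rare event and its raw count is
#' the signal.
#'
#' @param corpus an [si_corpus()]
#' @param emoji_lex an emoji [si_lexicon()] with a `risk` category
#' @return a `feature_block` tagged `BSC`
#' @export
emoji_features <- function(corpus, emoji_lex) {
  if (nrow(corpus) == 0) stop("empty corpus")
  stopifnot(emoji_lex$kind == "emoji")
  risk <- emoji_lex$categories$risk
  out <- matrix(0, nrow(corpus), length(risk) + 1,
                dimnames = list(NULL, c(paste0("emoji.", risk), "emoji.total")))
  for (j in seq_along(risk)) {
    out[, j] <- vapply(corpus$emojis, function(e) sum(e == risk[j]), 0)
  }
  out[, length(risk) + 1] <- lengths(corpus$emojis)
  feature_block(out, "BSC", corpus$id)
}

#' Time-of-day bin features
#'
#' The day is split into 8 fixed 3-hour periods; bin i covers hours
#' `[3i, 3i+3)` with bin 0 anchored at midnight. Each post gets a one-hot
#' row over the 8 bins.
#'
#' @param corpus an [si_corpus()]
#' @return an 8-column one-hot `feature_block` tagged `BSC`
#' @export
time_bin_features <- function(corpus) {
  if (nrow(corpus) == 0) stop("empty corpus")
  if (anyNA(corpus$hour)) {
    stop("missing timestamp for post(s): ",
         paste(head(corpus$id[is.na(corpus$hour)], 5), collapse = ", "))
  }
  bin <- corpus$hour %/% 3L
  out <- matrix(0, nrow(corpus), 8,
                dimnames = list(NULL, sprintf("time.bin%d", 0:7)))
  out[cbind(seq_len(nrow(corpus)), bin + 1L)] <- 1
  feature_block(out, "BSC", corpus$id)
}

#' Full basic-statistical-characteristics block
#'
#' Horizontal concatenation of the five BSC sub-blocks: LIWC-style category
#' rates, sentiment rates, degree-adverb rates, emoji counts, and time bins.
#'
#' @param corpus an [si_corpus()]
#' @param lexicons named lexicon list as from [make_fixture_lexicons()]
#'   (needs `liwc`, `polarity`, `degree`, `emoji`)
#' @return a `feature_block` with every column tagged `BSC`
#' @export
bsc_block <- function(corpus, lexicons) {
  cbind_blocks(
    liwc_category_features(corpus, lexicons$liwc),
    polarity_features(corpus, lexicons$polarity),
    degree_adverb_features(corpus, lexicons$degree),
    emoji_features(corpus, lexicons$emoji),
    time_bin_features(corpus)
  )
}
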