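#' Configuration for the synthetic corpus generator
#'
#' The generator emulates the statistical shape of an imbalanced microblog
#' dataset annotated for suicidal ideation: a small positive class
#' (default 2,272 posts) against a large negative class (default 37,950),
#' class-conditional enrichment of risk-dictionary and negative-sentiment
#' vocabulary in positive posts, a night-shifted posting-time distribution
#' for the positive class, and latent-topic co-occurrence structure strong
#' enough for skip-gram embeddings to place topically related words near
#' each other.
#'
#' Enrichment multipliers are keyed `"<lexicon-kind>:<category>"`, with `"*"`
#' matching every category of a kind. A multiplier m scales the positive
#' class's token-emission probability for that category relative to the
#' negative class (m = 1 means no class signal).
#'
#' @param n_pos number of positive (suicidal-ideation) posts
#' @param n_neg number of negative posts
#' @param seed integer seed; all generator randomness flows from it
#' @param n_topics number of latent background topics
#' @param topic_vocab words per topic
#' @param liwc_categories number of LIWC-style categories in the fixture
#'   category lexicon
#' @param words_per_category entries per fixture lexicon category
#' @param length_meanlog,length_sdlog log-normal token-count parameters
#'   (defaults give a mean post length of about 25 tokens)
#' @param enrichment named numeric vector of positive-class rate multipliers
#' @param time_skew_neg,time_skew_pos per-class probabilities over the 8
#'   three-hour time bins (must each sum to 1)
#' @param emoji_rate_neg,emoji_rate_pos Poisson mean emoji count per post
#' @param risk_emoji_share_neg,risk_emoji_share_pos probability that an
#'   emitted emoji is a risk emoji rather than a common one
#' @return an object of class `si_generator_config`
#' @export
generator_config <- function(n_pos = 2272L,
                             n_neg = 37950L,
                             seed = 1L,
                             n_topics = 8L,
                             topic_vocab = 30L,
                             liwc_categories = 7L,
                             words_per_category = 15L,
                             length_meanlog = log(25) - 0.08,
                             length_sdlog = 0.4,
                             enrichment = c("risk-dictionary:*" = 6,
                                            "polarity:negative" = 3,
                                            "polarity:positive" = 0.6),
                             time_skew_neg = c(0.03, 0.02, 0.05, 0.14,
                                               0.18, 0.18, 0.21, 0.19),
                             time_skew_pos = c(0.17, 0.12, 0.07, 0.07,
                                               0.09, 0.12, 0.14, 0.22),
                             emoji_rate_neg = 0.3,
                             emoji_rate_pos = 0.6,
                             risk_emoji_share_neg = 0.05,
                             risk_emoji_share_pos = 0.45) {
  cfg <- list(n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
              seed = as.integer(seed), n_topics = as.integer(n_topics),
              topic_vocab = as.integer(topic_vocab),
              liwc_categories = as.integer(liwc_categories),
              words_per_category = as.integer(words_per_category),
              length_meanlog = length_meanlog, length_sdlog = length_sdlog,
              enrichment = enrichment,
              time_skew_neg = time_skew_neg, time_skew_pos = time_skew_pos,
              emoji_rate_neg = emoji_rate_neg, emoji_rate_pos = emoji_rate_pos,
              risk_emoji_share_neg = risk_emoji_share_neg,
              risk_emoji_share_pos = risk_emoji_share_pos)
  if (cfg$n_pos <= 0 || cfg$n_neg <= 0) stop("n_pos and n_neg must be positive")
  if (any(enrichment <= 0)) stop("enrichment multipliers must be > 0")
  for (nm in c("time_skew_neg", "time_skew_pos")) {
    p <- cfg[[nm]]
    if (length(p) != 8 || abs(sum(p) - 1) > 1e-8 || any(p < 0)) {
      stop(nm, " must be 8 non-negative probabilities summing to 1")
    }
  }
  structure(cfg, class = "si_generator_config")
}

risk_emoji_names <- c("Drugs", "Knife", "Rope", "Pills", "Blade", "Bridge")
common_emoji_names <- c("Smile", "Heart", "Laugh", "Sun", "Cake", "Star",
                        "Rain", "Moon", "Dog", "Coffee")

#' Generate the fixture lexicon set
#'
#' Produces synthetic-word lexicons with the structure the feature extractors
#' require: a LIWC-style category lexicon, a merged polarity lexicon, a
#' 4-level degree-adverb lexicon, an emoji lexicon flagging risk emojis, and
#' a 13-category suicide-risk dictionary. All word entries are synthetic
#' tokens disjoint from the generator's background-topic vocabulary.
#'
#' @param config an [generator_config()]
#' @return named list of [si_lexicon()] objects
#'   (`liwc`, `polarity`, `degree`, `emoji`, `risk`)
#' @export
make_fixture_lexicons <- function(config = generator_config()) {
  stopifnot(inherits(config, "si_generator_config"))
  wpc <- config$words_per_category
  liwc_names <- c("affect", "cogproc", "social", "family", "health",
                  "body", "work", "leisure", "money", "percept")[seq_len(config$liwc_categories)]
  mk_words <- function(prefix, n) sprintf("%s_w%02d", prefix, seq_len(n))
  liwc <- si_lexicon("synthetic-liwc",
                     stats::setNames(lapply(liwc_names, function(cn) mk_words(paste0("liwc_", cn), wpc)),
                                     liwc_names),
                     "category-count")
  polarity <- si_lexicon("synthetic-polarity",
                         list(positive = mk_words("posw", 40),
                              negative = mk_words("negw", 40)),
                         "polarity")
  degree <- si_lexicon("synthetic-degree",
                       stats::setNames(lapply(1:4, function(l) mk_words(sprintf("deg%d", l), 6)),
                                       paste0("level", 1:4)),
                       "degree-adverb")
  emoji <- si_lexicon("synthetic-emoji",
                      list(risk = risk_emoji_names, common = common_emoji_names),
                      "emoji")
  risk <- si_lexicon("synthetic-risk-dictionary",
                     stats::setNames(lapply(1:13, function(j) mk_words(sprintf("risk_c%02d", j), 10)),
                                     sprintf("risk%02d", 1:13)),
                     "risk-dictionary")
  list(liwc = liwc, polarity = polarity, degree = degree,
       emoji = emoji, risk = risk)
}

# Per-class token-emission probabilities over word pools. Pools are the
# latent topics (background content), a common function-word pool, and the
# word lexicons; positive-class category rates are the negative-class rates
# scaled by the enrichment multipliers and renormalized.
token_pools <- function(config, lexicons) {
  pools <- list()
  rates0 <- numeric(0)
  add <- function(pools, name, words, rate) {
    pools[[name]] <- words
    rates0[[name]] <<- rate
    pools
  }
  for (j in seq_len(config$n_topics)) {
    pools <- add(pools, sprintf("topic:%d", j),
                 sprintf("t%02dw%02d", j, seq_len(config$topic_vocab)), NA)
  }
  pools <- add(pools, "common", sprintf("fw%02d", 1:40), 0.22)
  for (cn in names(lexicons$liwc$categories)) {
    pools <- add(pools, paste0("category-count:", cn),
                 lexicons$liwc$categories[[cn]],
                 0.10 / length(lexicons$liwc$categories))
  }
  pools <- add(pools, "polarity:positive", lexicons$polarity$categories$positive, 0.040)
  pools <- add(pools, "polarity:negative", lexicons$polarity$categories$negative, 0.030)
  for (ln in names(lexicons$degree$categories)) {
    pools <- add(pools, paste0("degree-adverb:", ln),
                 lexicons$degree$categories[[ln]], 0.030 / 4)
  }
  for (cn in names(lexicons$risk$categories)) {
    pools <- add(pools, paste0("risk-dictionary:", cn),
                 lexicons$risk$categories[[cn]], 0.012 / 13)
  }
  # remaining probability mass goes to the per-post latent topic
  topic_mass <- 1 - sum(rates0, na.rm = TRUE)
  stopifnot(topic_mass > 0)
  rates1 <- rates0
  for (key in names(config$enrichment)) {
    parts <- strsplit(key, ":", fixed = TRUE)[[1]]
    kind <- parts[1]; cat <- parts[2]
    hit <- if (cat == "*") {
      grepl(paste0("^", kind, ":"), names(rates1))
    } else {
      names(rates1) == key
    }
    rates1[hit & !is.na(rates1)] <- rates1[hit & !is.na(rates1)] * config$enrichment[[key]]
  }
  # renormalize lexicon+common mass within (1 - topic_mass) is NOT done:
  # instead topic mass absorbs the difference so that absolute per-category
  # rates scale exactly by the multiplier (keeps enrichment interpretable)
  topic_mass1 <- 1 - sum(rates1, na.rm = TRUE)
  if (topic_mass1 <= 0) stop("enrichment multipliers leave no mass for topic words")
  list(pools = pools, rates_neg = rates0, rates_pos = rates1,
       topic_mass_neg = topic_mass, topic_mass_pos = topic_mass1)
}

# POS tag per pool: content-word tags on lexicon/topic words, function tag on
# the common pool; degree adverbs tagged "d".
pool_pos_tag <- function(pool_name) {
  if (pool_name == "common") return("u")
  if (grepl("^degree-adverb:", pool_name)) return("d")
  if (grepl("^polarity:", pool_name)) return("a")
  if (grepl("^topic:", pool_name)) return("n")
  if (grepl("^risk-dictionary:", pool_name)) return("n")
  "v"
}

generate_class <- function(n, class_label, config, tp, lexicons) {
  rates <- if (class_label == 1L) tp$rates_pos else tp$rates_neg
  topic_mass <- if (class_label == 1L) tp$topic_mass_pos else tp$topic_mass_neg
  lens <- pmax(5L, as.integer(round(rlnorm(n, config$length_meanlog, config$length_sdlog))))
  total <- sum(lens)
  post_of <- rep.int(seq_len(n), lens)
  topic_of_post <- sample.int(config$n_topics, n, replace = TRUE)

  pool_names <- names(tp$pools)
  lex_pools <- pool_names[!grepl("^topic:", pool_names)]
  probs <- c(topic_mass, unname(rates[lex_pools]))
  src <- sample.int(length(lex_pools) + 1L, total, replace = TRUE, prob = probs)

  tokens <- character(total)
  tags <- character(total)
  is_topic <- src == 1L
  if (any(is_topic)) {
    tpost <- topic_of_post[post_of[is_topic]]
    idx <- sample.int(config$topic_vocab, sum(is_topic), replace = TRUE)
    tokens[is_topic] <- sprintf("t%02dw%02d", tpost, idx)
    tags[is_topic] <- "n"
  }
  for (s in seq_along(lex_pools)) {
    sel <- src == s + 1L
    if (!any(sel)) next
    pool <- tp$pools[[lex_pools[s]]]
    tokens[sel] <- pool[sample.int(length(pool), sum(sel), replace = TRUE)]
    tags[sel] <- pool_pos_tag(lex_pools[s])
  }
  token_list <- split(tokens, post_of)
  tag_list <- split(tags, post_of)

  # timestamps: draw a 3-hour bin from the class skew, then uniform within
  skew <- if (class_label == 1L) config$time_skew_pos else config$time_skew_neg
  bin <- sample.int(8L, n, replace = TRUE, prob = skew) - 1L
  hour <- bin * 3L + sample.int(3L, n, replace = TRUE) - 1L
  minute <- sample.int(60L, n, replace = TRUE) - 1L

  # emojis: Poisson count, risk-vs-common mixture
  rate <- if (class_label == 1L) config$emoji_rate_pos else config$emoji_rate_neg
  share <- if (class_label == 1L) config$risk_emoji_share_pos else config$risk_emoji_share_neg
  n_emo <- stats::rpois(n, rate)
  emojis <- lapply(n_emo, function(k) {
    if (k == 0) return(character(0))
    risky <- runif(k) < share
    c(risk_emoji_names[sample.int(length(risk_emoji_names), sum(risky), replace = TRUE)],
      common_emoji_names[sample.int(length(common_emoji_names), sum(!risky), replace = TRUE)])
  })

  df <- data.frame(id = character(n), text = "", stringsAsFactors = FALSE)
  df$tokens <- unname(token_list)
  df$pos <- unname(tag_list)
  df$hour <- hour
  df$minute <- minute
  df$emojis <- emojis
  df$label <- rep.int(class_label, n)
  df
}

#' Generate a synthetic labeled corpus
#'
#' Draws `n_pos` positive and `n_neg` negative posts. Each token is emitted
#' either from the post's latent topic, from a common function-word pool, or
#' from one of the fixture lexicons; the positive class over-expresses
#' risk-dictionary and negative-sentiment words according to the enrichment
#' map, posts in each class follow their own time-of-day bin distribution,
#' and emoji draws over-represent risk emojis in the positive class. The
#' whole draw is a deterministic function of `config$seed`.
#'
#' @param config an [generator_config()]
#' @param lexicons fixture lexicons from [make_fixture_lexicons()]; generated
#'   from `config` when `NULL`
#' @return an [si_corpus()] with provenance `"synthetic:<seed>"`
#' @export
generate_corpus <- function(config = generator_config(), lexicons = NULL) {
  stopifnot(inherits(config, "si_generator_config"))
  if (is.null(lexicons)) lexicons <- make_fixture_lexicons(config)
  tp <- token_pools(config, lexicons)
  withr::with_seed(config$seed, {
    pos <- generate_class(config$n_pos, 1L, config, tp, lexicons)
    neg <- generate_class(config$n_neg, 0L, config, tp, lexicons)
    df <- rbind(pos, neg)
    ord <- sample.int(nrow(df))
    df <- df[ord, , drop = FALSE]
    df$id <- sprintf("p%06d", seq_len(nrow(df)))
    rownames(df) <- NULL
    si_corpus(df, provenance = paste0("synthetic:", config$seed))
  })
}
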