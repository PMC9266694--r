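#' Train skip-gram word embeddings on a corpus
#'
#' Trains skip-gram-with-negative-sampling embeddings on the corpus's token
#' sequences. Training is single-threaded and fully deterministic given the
#' seed. Words occurring fewer than `min_count` times are dropped from the
#' vocabulary.
#'
#' @param corpus an [si_corpus()]
#' @param dim embedding dimension (default 100)
#' @param window maximum context window; per-position windows are uniformly
#'   reduced, as is standard for skip-gram training
#' @param epochs training epochs
#' @param min_count minimum token frequency to keep a word
#' @param negative negative samples per positive pair
#' @param alpha initial learning rate (linearly decayed)
#' @param seed integer seed
#' @return an object of class `embedding_table` with `vocabulary` (words in
#'   decreasing frequency order), `vectors` (|V| x dim matrix, rows named by
#'   word) and the training config
#' @export
train_skipgram <- function(corpus, dim = 100L, window = 5L, epochs = 5L,
                           min_count = 2L, negative = 5L, alpha = 0.025,
                           seed = 1L) {
  if (nrow(corpus) == 0) stop("empty corpus")
  tokens <- corpus$tokens
  counts <- table(unlist(tokens))
  keep <- counts[counts >= min_count]
  if (length(keep) == 0) stop("vocabulary is empty after applying min_count")
  # decreasing frequency, ties alphabetical: a fixed, reproducible order
  ord <- order(-as.integer(keep), names(keep))
  vocab <- names(keep)[ord]
  vcounts <- as.numeric(keep)[ord]
  idx <- seq_along(vocab)
  names(idx) <- vocab
  sentences <- lapply(tokens, function(tk) {
    ids <- idx[tk]
    as.integer(ids[!is.na(ids)] - 1L)
  })
  sentences <- sentences[lengths(sentences) > 1]
  if (length(sentences) == 0) stop("no sentence has two or more in-vocabulary tokens")
  vec <- .sgns_train(sentences, vcounts, as.integer(dim), as.integer(window),
                     as.integer(epochs), as.integer(negative), alpha,
                     as.integer(seed))
  rownames(vec) <- vocab
  structure(list(vocabulary = vocab, vectors = vec,
                 config = list(dim = dim, window = window, epochs = epochs,
                               min_count = min_count, negative = negative,
                               alpha = alpha, seed = seed)),
            class = "embedding_table")
}

#' @exportS3Method print embedding_table
print.embedding_table <- function(x, ...) {
  cat(sprintf("<embedding_table> %d words x %d dims (window %d, %d epochs, seed %d)\n",
              length(x$vocabulary), x$config$dim, x$config$window,
              x$config$epochs, x$config$seed))
  invisible(x)
}

#' Write embeddings in word2vec text format
#'
#' First line `"<vocab> <dim>"`, then one `word v1 ... vd` line per word.
#'
#' @param embeddings an `embedding_table`
#' @param path destination file
#' @return `path`, invisibly
#' @export
write_embeddings <- function(embeddings, path) {
  v <- embeddings$vectors
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("%d %d", nrow(v), ncol(v)), con)
  for (i in seq_len(nrow(v))) {
    writeLines(paste(c(rownames(v)[i], formatC(v[i, ], format = "g", digits = 8)),
                     collapse = " "), con)
  }
  invisible(path)
}

#' Read embeddings from word2vec text format
#' @param path file written by [write_embeddings()] or any word2vec text file
#' @return an `embedding_table` (config fields unknown are NA)
#' @export
read_embeddings <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  hdr <- as.integer(strsplit(lines[1], " ", fixed = TRUE)[[1]])
  n <- hdr[1]; d <- hdr[2]
  parts <- strsplit(lines[1 + seq_len(n)], " ", fixed = TRUE)
  words <- vapply(parts, `[`, "", 1)
  vec <- t(vapply(parts, function(p) as.numeric(p[-1]), numeric(d)))
  rownames(vec) <- words
  structure(list(vocabulary = words, vectors = vec,
                 config = list(dim = d, window = NA, epochs = NA,
                               min_count = NA, negative = NA, alpha = NA,
                               seed = NA)),
            class = "embedding_table")
}
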