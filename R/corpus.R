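#' @useDynLib sidefuse, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats predict rbinom rlnorm rmultinom runif sd var aggregate
#' @importFrom utils head write.csv read.csv
NULL

#' Construct a post corpus
#'
#' A corpus is the unit container for labeled (or unlabeled) short posts.
#' Each post carries an id, optional raw text, an ordered token list, POS
#' tags aligned to the tokens, a time of day, an emoji list and an optional
#' binary label (1 = suicidal ideation, 0 = none).
#'
#' @param posts data.frame with columns `id` (character), `text` (character),
#'   `tokens` (list of character vectors), `pos` (list of character vectors),
#'   `hour` (integer 0-23), `minute` (integer 0-59), `emojis` (list of
#'   character vectors), `label` (integer 0/1 or NA).
#' @param provenance character scalar, e.g. a file path or `"synthetic:<seed>"`.
#' @return An object of class `si_corpus` (a data.frame with list columns).
#' @export
si_corpus <- function(posts, provenance = "memory") {
  required <- c("id", "text", "tokens", "pos", "hour", "minute", "emojis", "label")
  missing <- setdiff(required, names(posts))
  if (length(missing) > 0) {
    stop("corpus is missing column(s): ", paste(missing, collapse = ", "))
  }
  posts <- as.data.frame(posts[required], stringsAsFactors = FALSE)
  posts$id <- as.character(posts$id)
  if (anyDuplicated(posts$id)) {
    dup <- unique(posts$id[duplicated(posts$id)])
    stop("duplicate post id(s): ", paste(head(dup, 5), collapse = ", "))
  }
  n_tok <- lengths(posts$tokens)
  n_pos <- lengths(posts$pos)
  has_pos <- n_pos > 0
  bad <- which(has_pos & n_pos != n_tok)
  if (length(bad) > 0) {
    stop("pos_tags/token length mismatch for post(s): ",
         paste(head(posts$id[bad], 5), collapse = ", "))
  }
  if (any(n_tok == 0)) {
    stop("empty token list for post(s): ",
         paste(head(posts$id[n_tok == 0], 5), collapse = ", "))
  }
  lab <- posts$label
  if (!all(is.na(lab) | lab %in% c(0L, 1L))) {
    bad <- which(!(is.na(lab) | lab %in% c(0L, 1L)))
    stop("label outside {0,1} for post(s): ",
         paste(head(posts$id[bad], 5), collapse = ", "))
  }
  if (any(posts$hour < 0 | posts$hour > 23, na.rm = FALSE) || anyNA(posts$hour)) {
    stop("hour must be an integer in [0, 24) for every post")
  }
  if (any(posts$minute < 0 | posts$minute > 59)) {
    stop("minute must be in [0, 60)")
  }
  structure(posts, provenance = provenance,
            class = c("si_corpus", "data.frame"))
}

#' @exportS3Method print si_corpus
print.si_corpus <- function(x, ...) {
  n <- nrow(x)
  n_lab <- sum(!is.na(x$label))
  n_pos <- sum(x$label == 1L, na.rm = TRUE)
  cat(sprintf("<si_corpus> %d posts (%d labeled, %d positive)  provenance: %s\n",
              n, n_lab, n_pos, attr(x, "provenance")))
  invisible(x)
}

#' Number of posts in a corpus
#' @param corpus an `si_corpus`
#' @return integer count
#' @export
n_posts <- function(corpus) nrow(corpus)

#' Corpus labels as an integer vector
#' @param corpus an `si_corpus`
#' @return integer vector of 0/1 (NA where unlabeled)
#' @export
corpus_labels <- function(corpus) as.integer(corpus$label)

parse_hhmm <- function(x) {
  m <- regmatches(x, regexec("^([0-9]{1,2}):([0-9]{2})$", x))
  hh <- vapply(m, function(g) if (length(g) == 3) as.integer(g[2]) else NA_integer_, 1L)
  mm <- vapply(m, function(g) if (length(g) == 3) as.integer(g[3]) else NA_integer_, 1L)
  ok <- !is.na(hh) & !is.na(mm) & hh >= 0 & hh <= 23 & mm >= 0 & mm <= 59
  hh[!ok] <- NA_integer_
  mm[!ok] <- NA_integer_
  list(hour = hh, minute = mm)
}
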