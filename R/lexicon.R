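#' Construct a lexicon
#'
#' A lexicon maps category names to entry sets (words or emoji identifiers).
#' Five kinds are recognized, with kind-specific structural invariants:
#' `category-count` (any number of categories, LIWC-style), `polarity`
#' (exactly the categories `positive` and `negative`), `degree-adverb`
#' (exactly 4 intensity levels), `emoji` (flagged risk emojis), and
#' `risk-dictionary` (exactly 13 categories, mirroring the category structure
#' of published suicide-risk dictionaries).
#'
#' @param name lexicon name
#' @param categories named list of character vectors (entries deduplicated)
#' @param kind one of `"category-count"`, `"polarity"`, `"degree-adverb"`,
#'   `"emoji"`, `"risk-dictionary"`
#' @return an object of class `si_lexicon`
#' @export
si_lexicon <- function(name, categories,
                       kind = c("category-count", "polarity", "degree-adverb",
                                "emoji", "risk-dictionary")) {
  kind <- match.arg(kind)
  if (!is.list(categories) || is.null(names(categories)) ||
      any(!nzchar(names(categories)))) {
    stop("categories must be a named list of character vectors")
  }
  if (anyDuplicated(names(categories))) {
    stop("duplicate category name(s) in lexicon '", name, "'")
  }
  categories <- lapply(categories, function(v) {
    v <- unique(as.character(v))
    if (any(!nzchar(v))) stop("empty entry in lexicon '", name, "'")
    v
  })
  if (kind == "polarity" && !setequal(names(categories), c("positive", "negative"))) {
    stop("polarity lexicon must have exactly the categories {positive, negative}")
  }
  if (kind == "degree-adverb" && length(categories) != 4) {
    stop("degree-adverb lexicon must have exactly 4 categories, got ", length(categories))
  }
  if (kind == "risk-dictionary" && length(categories) != 13) {
    stop("risk-dictionary lexicon must have exactly 13 categories, got ", length(categories))
  }
  structure(list(name = name, kind = kind, categories = categories),
            class = "si_lexicon")
}

#' @exportS3Method print si_lexicon
print.si_lexicon <- function(x, ...) {
  cat(sprintf("<si_lexicon> '%s' (%s): %d categories, %d entries\n",
              x$name, x$kind, length(x$categories), sum(lengths(x$categories))))
  invisible(x)
}

#' Read a lexicon from TSV or JSON
#'
#' TSV format: one `category<TAB>entry` pair per line. JSON format: an object
#' mapping category name to an array of entries. Duplicate entries within a
#' category are deduplicated.
#'
#' @param path file path (`.tsv`/`.txt` or `.json`)
#' @param name lexicon name; default is the file stem
#' @param kind declared lexicon kind (validates kind-specific invariants)
#' @return an [si_lexicon()]
#' @export
read_lexicon <- function(path, name = NULL,
                         kind = c("category-count", "polarity", "degree-adverb",
                                  "emoji", "risk-dictionary")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(name)) name <- sub("\\.[^.]+$", "", basename(path))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
    categories <- lapply(obj, as.character)
  } else {
    lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
    lines <- lines[nzchar(trimws(lines))]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    bad <- which(lengths(parts) != 2)
    if (length(bad) > 0) {
      stop("malformed TSV line(s) ", paste(head(bad, 5), collapse = ", "),
           " in ", path, " (expected category<TAB>entry)")
    }
    cat_names <- vapply(parts, `[`, "", 1)
    entries <- vapply(parts, `[`, "", 2)
    categories <- split(entries, factor(cat_names, levels = unique(cat_names)))
    categories <- lapply(categories, as.character)
  }
  si_lexicon(name, categories, kind)
}

#' Write a lexicon to TSV
#' @param lexicon an [si_lexicon()]
#' @param path destination file
#' @return `path`, invisibly
#' @export
write_lexicon <- function(lexicon, path) {
  lines <- unlist(lapply(names(lexicon$categories), function(cat) {
    paste(cat, lexicon$categories[[cat]], sep = "\t")
  }))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Merge several polarity lexicons by majority vote
#'
#' Sentiment resources frequently disagree on individual words. The merged
#' polarity of each word is the majority polarity across the source lexicons
#' that contain it; words with tied votes are excluded altogether.
#'
#' @param lexicons list of polarity [si_lexicon()] objects
#' @param name name for the merged lexicon
#' @return a polarity [si_lexicon()]
#' @export
merge_polarity_lexicons <- function(lexicons, name = "merged-polarity") {
  if (length(lexicons) == 0) stop("need at least one polarity lexicon")
  for (lx in lexicons) {
    if (!inherits(lx, "si_lexicon") || lx$kind != "polarity") {
      stop("all inputs must be polarity lexicons")
    }
  }
  votes <- new.env(parent = emptyenv())
  for (lx in lexicons) {
    for (w in lx$categories$positive) {
      v <- if (is.null(votes[[w]])) c(0L, 0L) else votes[[w]]
      votes[[w]] <- v + c(1L, 0L)
    }
    for (w in lx$categories$negative) {
      v <- if (is.null(votes[[w]])) c(0L, 0L) else votes[[w]]
      votes[[w]] <- v + c(0L, 1L)
    }
  }
  words <- sort(ls(votes))
  pos <- character(0); neg <- character(0)
  for (w in words) {
    v <- votes[[w]]
    if (v[1] > v[2]) pos <- c(pos, w)
    else if (v[2] > v[1]) neg <- c(neg, w)
    # ties dropped
  }
  si_lexicon(name, list(positive = pos, negative = neg), "polarity")
}

#' Find a lexicon of a given kind (and optionally name) in a list
#' @param lexicons list of [si_lexicon()]
#' @param kind lexicon kind to look for
#' @param name optional name filter
#' @return the first matching lexicon
#' @export
find_lexicon <- function(lexicons, kind, name = NULL) {
  for (lx in lexicons) {
    if (lx$kind == kind && (is.null(name) || lx$name == name)) return(lx)
  }
  stop("no lexicon of kind '", kind, "'",
       if (!is.null(name)) paste0(" named '", name, "'") else "", " found")
}
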