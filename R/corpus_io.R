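#' Read a corpus from disk
#'
#' Two on-disk formats are supported. JSONL is canonical: one JSON object per
#' line with keys `id`, `text`, `tokens`, `pos`, `time` (`"HH:MM"`), `emojis`,
#' `label` (may be null). CSV is a convenience format with the same columns,
#' where `tokens`, `pos` and `emojis` are `|`-joined strings.
#'
#' Rows with unparseable timestamps or empty token lists are rejected with a
#' per-row diagnostic; missing required fields and duplicate ids are errors.
#'
#' @param path file path
#' @param format `"jsonl"` or `"csv"`; default guessed from the extension
#' @return an [si_corpus()]
#' @export
read_corpus <- function(path, format = c("auto", "jsonl", "csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "jsonl"
  }
  if (format == "jsonl") {
    lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0) stop("empty corpus file: ", path)
    rows <- lapply(seq_along(lines), function(i) {
      rec <- tryCatch(jsonlite::fromJSON(lines[i], simplifyVector = TRUE),
                      error = function(e) stop("row ", i, ": unparseable JSON (", conditionMessage(e), ")"))
      for (key in c("id", "tokens", "time")) {
        if (is.null(rec[[key]])) stop("row ", i, ": missing required field '", key, "'")
      }
      rec
    })
    df <- data.frame(
      id = vapply(rows, function(r) as.character(r$id), ""),
      text = vapply(rows, function(r) if (is.null(r$text)) "" else as.character(r$text), ""),
      stringsAsFactors = FALSE
    )
    df$tokens <- lapply(rows, function(r) as.character(unlist(r$tokens)))
    df$pos <- lapply(rows, function(r) as.character(unlist(r$pos)))
    tm <- parse_hhmm(vapply(rows, function(r) as.character(r$time), ""))
    df$hour <- tm$hour
    df$minute <- tm$minute
    df$emojis <- lapply(rows, function(r) as.character(unlist(r$emojis)))
    df$label <- vapply(rows, function(r) {
      if (is.null(r$label) || length(r$label) == 0 || is.na(r$label)) NA_integer_ else as.integer(r$label)
    }, 1L)
  } else {
    raw <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
    required <- c("id", "text", "tokens", "pos", "time", "emojis", "label")
    missing <- setdiff(required, names(raw))
    if (length(missing) > 0) stop("csv corpus missing column(s): ", paste(missing, collapse = ", "))
    split_bar <- function(x) lapply(x, function(s) if (is.na(s) || !nzchar(s)) character(0) else strsplit(s, "|", fixed = TRUE)[[1]])
    tm <- parse_hhmm(raw$time)
    df <- data.frame(id = raw$id, text = raw$text, stringsAsFactors = FALSE)
    df$tokens <- split_bar(raw$tokens)
    df$pos <- split_bar(raw$pos)
    df$hour <- tm$hour
    df$minute <- tm$minute
    df$emojis <- split_bar(raw$emojis)
    df$label <- ifelse(is.na(raw$label) | raw$label == "", NA_integer_, suppressWarnings(as.integer(raw$label)))
  }
  bad_time <- which(is.na(df$hour))
  if (length(bad_time) > 0) {
    stop("unparseable timestamp in row(s) ", paste(head(bad_time, 5), collapse = ", "),
         " (id: ", paste(head(df$id[bad_time], 5), collapse = ", "), ")")
  }
  empty <- which(lengths(df$tokens) == 0)
  if (length(empty) > 0) {
    stop("empty token list in row(s) ", paste(head(empty, 5), collapse = ", "),
         " (id: ", paste(head(df$id[empty], 5), collapse = ", "), ")")
  }
  si_corpus(df, provenance = path)
}

#' Write a corpus to disk
#'
#' @param corpus an [si_corpus()]
#' @param path destination file
#' @param format `"jsonl"` (canonical) or `"csv"`
#' @return `path`, invisibly
#' @export
write_corpus <- function(corpus, path, format = c("jsonl", "csv")) {
  format <- match.arg(format)
  time_str <- sprintf("%02d:%02d", corpus$hour, corpus$minute)
  if (format == "jsonl") {
    lines <- vapply(seq_len(nrow(corpus)), function(i) {
      jsonlite::toJSON(list(
        id = jsonlite::unbox(corpus$id[i]),
        text = jsonlite::unbox(corpus$text[i]),
        tokens = corpus$tokens[[i]],
        pos = corpus$pos[[i]],
        time = jsonlite::unbox(time_str[i]),
        emojis = corpus$emojis[[i]],
        label = if (is.na(corpus$label[i])) NULL else jsonlite::unbox(corpus$label[i])
      ), null = "null")
    }, "")
    writeLines(lines, path, useBytes = TRUE)
  } else {
    join_bar <- function(col) vapply(col, paste, "", collapse = "|")
    out <- data.frame(
      id = corpus$id, text = corpus$text,
      tokens = join_bar(corpus$tokens), pos = join_bar(corpus$pos),
      time = time_str, emojis = join_bar(corpus$emojis),
      label = ifelse(is.na(corpus$label), "", as.character(corpus$label)),
      stringsAsFactors = FALSE
    )
    utils::write.csv(out, path, row.names = FALSE)
  }
  invisible(path)
}
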