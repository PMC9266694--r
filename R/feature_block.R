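#' Construct a feature block
#'
#' A feature block is a numeric post-by-feature matrix annotated with the
#' family each column comes from (`BSC`, `RFS` or `WEC`) and the post ids of
#' its rows. All downstream combination and selection steps preserve these
#' tags so column provenance is never lost.
#'
#' @param matrix numeric matrix, rows = posts, columns = features; must have
#'   unique column names and contain no NA/NaN/Inf
#' @param block character vector (length = ncol) of family tags, or a single
#'   tag recycled to all columns
#' @param row_ids character vector of post ids (length = nrow)
#' @return an object of class `feature_block`
#' @export
feature_block <- function(matrix, block, row_ids) {
  if (!is.matrix(matrix) || !is.numeric(matrix)) stop("matrix must be a numeric matrix")
  if (is.null(colnames(matrix)) || anyDuplicated(colnames(matrix))) {
    stop("feature matrix must have unique column names")
  }
  if (any(!is.finite(matrix))) stop("feature matrix contains NA/NaN/Inf")
  if (length(block) == 1) block <- rep(block, ncol(matrix))
  if (length(block) != ncol(matrix)) stop("block tags must match column count")
  if (!all(block %in% c("BSC", "RFS", "WEC", "META"))) {
    stop("unknown block tag(s): ", paste(setdiff(block, c("BSC", "RFS", "WEC", "META")), collapse = ", "))
  }
  if (length(row_ids) != nrow(matrix)) stop("row_ids must match row count")
  structure(list(matrix = matrix, block = unname(block),
                 row_ids = as.character(row_ids)),
            class = "feature_block")
}

#' @exportS3Method print feature_block
print.feature_block <- function(x, ...) {
  tab <- table(x$block)
  cat(sprintf("<feature_block> %d posts x %d features (%s)\n",
              nrow(x$matrix), ncol(x$matrix),
              paste(sprintf("%s:%d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

#' @export
dim.feature_block <- function(x) dim(x$matrix)

#' Concatenate feature blocks column-wise
#'
#' @param ... `feature_block` objects over the same posts in the same order
#' @return a `feature_block` with all columns, tags preserved
#' @export
cbind_blocks <- function(...) {
  blocks <- list(...)
  if (length(blocks) == 1 && is.list(blocks[[1]]) && !inherits(blocks[[1]], "feature_block")) {
    blocks <- blocks[[1]]
  }
  stopifnot(length(blocks) >= 1)
  ids <- blocks[[1]]$row_ids
  for (b in blocks) {
    if (!identical(b$row_ids, ids)) stop("feature blocks cover different posts or orders")
  }
  feature_block(do.call(cbind, lapply(blocks, `[[`, "matrix")),
                unlist(lapply(blocks, `[[`, "block")),
                ids)
}

#' Subset the columns of a feature block
#' @param block a `feature_block`
#' @param cols column names or indices to keep
#' @return the reduced `feature_block`
#' @export
select_columns <- function(block, cols) {
  if (is.character(cols)) {
    idx <- match(cols, colnames(block$matrix))
    if (anyNA(idx)) stop("unknown column(s): ", paste(cols[is.na(idx)], collapse = ", "))
  } else idx <- cols
  feature_block(block$matrix[, idx, drop = FALSE], block$block[idx], block$row_ids)
}

#' Write a feature block to CSV with a sidecar JSON of column tags
#' @param block a `feature_block`
#' @param path CSV destination; tags go to `<path>.meta.json`
#' @return `path`, invisibly
#' @export
write_feature_block <- function(block, path) {
  df <- as.data.frame(block$matrix)
  df <- cbind(data.frame(id = block$row_ids, stringsAsFactors = FALSE), df)
  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(
    list(columns = colnames(block$matrix), block = block$block),
    paste0(path, ".meta.json"))
  invisible(path)
}

#' Read a feature block written by [write_feature_block()]
#' @param path CSV path
#' @return a `feature_block`
#' @export
read_feature_block <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  meta <- jsonlite::fromJSON(paste0(path, ".meta.json"))
  m <- as.matrix(df[, meta$columns, drop = FALSE])
  feature_block(m, meta$block, df$id)
}
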