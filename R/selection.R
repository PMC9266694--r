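# Extremely-randomized-trees feature selection and the three combination
# regimes: direct concatenation, select-then-combine, combine-then-select.

#' Selection configuration
#'
#' @param n_trees trees in the importance forest
#' @param criterion impurity criterion, `"gini"` or `"entropy"`
#' @param top_k keep the k most important columns (exclusive with `fraction`)
#' @param fraction keep the smallest importance-ranked prefix whose cumulative
#'   importance reaches this fraction (default 0.95)
#' @param seed integer seed
#' @return an object of class `selection_config`
#' @export
selection_config <- function(n_trees = 500L, criterion = c("gini", "entropy"),
                             top_k = NULL, fraction = if (is.null(top_k)) 0.95 else NULL,
                             seed = 1L) {
  criterion <- match.arg(criterion)
  if (!is.null(top_k) && !is.null(fraction)) stop("give top_k or fraction, not both")
  if (!is.null(top_k) && top_k < 1) stop("top_k must be positive")
  if (!is.null(fraction) && (fraction <= 0 || fraction > 1)) {
    stop("fraction must lie in (0, 1]")
  }
  structure(list(n_trees = as.integer(n_trees), criterion = criterion,
                 top_k = top_k, fraction = fraction, seed = as.integer(seed)),
            class = "selection_config")
}

#' Fit an importance-based feature selector
#'
#' Grows an extremely-randomized-trees forest on the block, ranks columns by
#' normalized impurity-decrease importance, and records the kept prefix
#' according to the keep rule (top-k count or cumulative-importance
#' fraction).
#'
#' @param block a `feature_block`
#' @param labels integer 0/1 labels aligned with the block rows
#' @param config a [selection_config()]
#' @return an object of class `feature_selector` with `kept` (column names in
#'   decreasing importance), `importances` (full, sums to 1) and `config`
#' @export
fit_importance_selector <- function(block, labels, config = selection_config()) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) stop("labels contain a single class; cannot rank features")
  if (length(labels) != nrow(block$matrix)) stop("labels do not match block rows")
  forest <- sf_forest(block$matrix, labels, n_trees = config$n_trees,
                      criterion = config$criterion, split = "random",
                      bootstrap = FALSE, seed = config$seed)
  imp <- forest$importance
  ord <- order(-imp, names(imp)) # deterministic tie-break by name
  ranked <- imp[ord]
  if (!is.null(config$top_k)) {
    kept <- names(ranked)[seq_len(min(config$top_k, length(ranked)))]
  } else {
    cum <- cumsum(ranked)
    n_keep <- which(cum >= config$fraction - 1e-12)[1]
    if (is.na(n_keep)) n_keep <- length(ranked)
    kept <- names(ranked)[seq_len(max(1L, n_keep))]
  }
  structure(list(kept = kept, importances = imp, config = config),
            class = "feature_selector")
}

#' Apply a fitted selector to a feature block
#' @param selector a `feature_selector`
#' @param block a `feature_block` containing the selector's kept columns
#' @return the reduced `feature_block` (kept columns, importance order)
#' @export
apply_selector <- function(selector, block) {
  select_columns(block, selector$kept)
}

#' Parse a combination-recipe string
#'
#' Accepts the field notation for feature-set recipes:
#' `"BSC+RFS"` (direct concatenation), `"(BSC-fs)+(RFS-fs)"`
#' (select-then-combine), `"(BSC+RFS)-fs"` (combine-then-select), and the
#' one-block forms `"BSC"` / `"BSC-fs"`.
#'
#' @param text recipe string
#' @param selection a [selection_config()] used wherever `-fs` appears
#' @return an object of class `combination_recipe` with `blocks`, `mode`
#'   (`"direct"`, `"select-then-combine"`, `"combine-then-select"`),
#'   `selection`, and the canonical `label`
#' @export
parse_recipe <- function(text, selection = selection_config()) {
  s <- gsub(" ", "", text)
  known <- c("BSC", "RFS", "WEC")
  if (grepl("^\\(([A-Z]+(\\+[A-Z]+)*)\\)-fs$", s)) {
    inner <- sub("^\\(", "", sub("\\)-fs$", "", s))
    blocks <- strsplit(inner, "+", fixed = TRUE)[[1]]
    mode <- "combine-then-select"
  } else if (grepl("^\\([A-Z]+-fs\\)(\\+\\([A-Z]+-fs\\))*$", s)) {
    blocks <- regmatches(s, gregexpr("[A-Z]+", s))[[1]]
    mode <- "select-then-combine"
  } else if (grepl("^[A-Z]+-fs$", s)) {
    blocks <- sub("-fs$", "", s)
    mode <- "select-then-combine"
  } else if (grepl("^[A-Z]+(\\+[A-Z]+)*$", s)) {
    blocks <- strsplit(s, "+", fixed = TRUE)[[1]]
    mode <- "direct"
  } else {
    stop("cannot parse recipe: '", text, "'")
  }
  bad <- setdiff(blocks, known)
  if (length(bad) > 0) stop("unknown feature famil(ies): ", paste(bad, collapse = ", "))
  if (anyDuplicated(blocks)) stop("repeated block in recipe: '", text, "'")
  combination_recipe(blocks, mode, selection)
}

#' Construct a combination recipe
#' @param blocks subset of `c("BSC", "RFS", "WEC")`
#' @param mode combination regime
#' @param selection a [selection_config()] (used by the `-fs` modes)
#' @return a `combination_recipe`
#' @export
combination_recipe <- function(blocks,
                               mode = c("direct", "select-then-combine",
                                        "combine-then-select"),
                               selection = selection_config()) {
  mode <- match.arg(mode)
  blocks <- as.character(blocks)
  if (length(blocks) == 0) stop("recipe needs at least one block")
  if (!all(blocks %in% c("BSC", "RFS", "WEC"))) stop("unknown block tag")
  label <- switch(mode,
    direct = paste(blocks, collapse = " + "),
    `select-then-combine` = if (length(blocks) == 1) paste0(blocks, "-fs")
                            else paste(sprintf("(%s-fs)", blocks), collapse = " + "),
    `combine-then-select` = if (length(blocks) == 1) paste0(blocks, "-fs")
                            else sprintf("(%s)-fs", paste(blocks, collapse = " + "))
  )
  structure(list(blocks = blocks, mode = mode, selection = selection,
                 label = label),
            class = "combination_recipe")
}

#' @exportS3Method print combination_recipe
print.combination_recipe <- function(x, ...) {
  cat(sprintf("<combination_recipe> %s  [%s]\n", x$label, x$mode))
  invisible(x)
}

#' Apply a combination recipe to feature blocks
#'
#' `direct` concatenates the named blocks; `select-then-combine` fits one
#' selector per block then concatenates the survivors;
#' `combine-then-select` concatenates first and fits a single selector on
#' the joint matrix. Column family tags are preserved throughout.
#'
#' @param recipe a `combination_recipe`
#' @param blocks named list of `feature_block`s (names `BSC`, `RFS`, `WEC`)
#' @param labels integer 0/1 labels (required by the `-fs` modes)
#' @return a `feature_block`
#' @export
apply_recipe <- function(recipe, blocks, labels = NULL) {
  missing <- setdiff(recipe$blocks, names(blocks))
  if (length(missing) > 0) stop("missing feature block(s): ", paste(missing, collapse = ", "))
  parts <- blocks[recipe$blocks]
  if (recipe$mode == "direct") {
    return(cbind_blocks(parts))
  }
  if (is.null(labels)) stop("recipe mode '", recipe$mode, "' needs labels for selection")
  if (recipe$mode == "select-then-combine") {
    reduced <- lapply(parts, function(b) {
      apply_selector(fit_importance_selector(b, labels, recipe$selection), b)
    })
    return(cbind_blocks(reduced))
  }
  joint <- cbind_blocks(parts)
  apply_selector(fit_importance_selector(joint, labels, recipe$selection), joint)
}
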