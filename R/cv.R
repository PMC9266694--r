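# Stratified cross-validation, pooled classification metrics, and
# best-model selection over the zoo.

#' Binary classification metrics
#'
#' Accuracy, precision, recall and F1 with the suicidal class (label 1) as
#' the positive class. Precision/recall/F1 are 0 when their denominator is 0.
#'
#' @param truth integer 0/1 truth
#' @param pred integer 0/1 predictions
#' @return named numeric vector `accuracy`, `f1`, `precision`, `recall`
#' @export
classification_metrics <- function(truth, pred) {
  truth <- as.integer(truth); pred <- as.integer(pred)
  stopifnot(length(truth) == length(pred))
  tp <- sum(truth == 1L & pred == 1L)
  fp <- sum(truth == 0L & pred == 1L)
  fn <- sum(truth == 1L & pred == 0L)
  tn <- sum(truth == 0L & pred == 0L)
  metrics_from_confusion(tp, fp, fn, tn)
}

#' Metrics from confusion counts
#' @param tp,fp,fn,tn confusion-matrix counts (positive class = 1)
#' @return named numeric vector `accuracy`, `f1`, `precision`, `recall`
#' @export
metrics_from_confusion <- function(tp, fp, fn, tn) {
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  accuracy <- (tp + tn) / (tp + fp + fn + tn)
  c(accuracy = accuracy, f1 = f1, precision = precision, recall = recall)
}

#' Stratified fold assignment
#'
#' Assigns each row to one of `k` folds, preserving the class balance in
#' every fold. The assignment depends only on `(labels, k, seed)`, so every
#' model evaluated under the same seed sees identical folds and leaderboards
#' are paired comparisons.
#'
#' @param labels integer 0/1 labels
#' @param k number of folds
#' @param seed integer seed
#' @return integer vector of fold ids (1..k)
#' @export
stratified_folds <- function(labels, k = 5L, seed = 1L) {
  labels <- as.integer(labels)
  n <- length(labels)
  if (n < k) stop("fewer rows than folds")
  counts <- table(labels)
  if (any(counts < k)) {
    stop("class with fewer than k members; stratified ", k,
         "-fold split impossible (change k or provide more data)")
  }
  fold <- integer(n)
  withr::with_seed(seed, {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      idx <- sample(idx)
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

# Per-fold train/test feature matrices for a recipe over raw family blocks.
# With in_fold_selection (the default, leakage-safe policy) any -fs selector
# is refit on the fold's training rows only; paper-style whole-data selection
# is available via in_fold_selection = FALSE.
recipe_fold_features <- function(recipe, blocks, labels, fold,
                                 in_fold_selection = TRUE) {
  k <- max(fold)
  if (recipe$mode == "direct" || !in_fold_selection) {
    full <- apply_recipe(recipe, blocks, labels)
    return(lapply(seq_len(k), function(f) {
      list(train = full$matrix[fold != f, , drop = FALSE],
           test = full$matrix[fold == f, , drop = FALSE])
    }))
  }
  lapply(seq_len(k), function(f) {
    tr <- fold != f
    sub_blocks <- lapply(blocks, function(b) {
      feature_block(b$matrix[tr, , drop = FALSE], b$block, b$row_ids[tr])
    })
    selected <- apply_recipe(recipe, sub_blocks, labels[tr])
    kept <- colnames(selected$matrix)
    full_test <- cbind_blocks(blocks[recipe$blocks])
    list(train = selected$matrix,
         test = full_test$matrix[!tr, kept, drop = FALSE])
  })
}

block_fold_features <- function(x, fold) {
  k <- max(fold)
  lapply(seq_len(k), function(f) {
    list(train = x[fold != f, , drop = FALSE],
         test = x[fold == f, , drop = FALSE])
  })
}

# Core CV loop over precomputed per-fold matrices; pools out-of-fold
# predictions for the pooled metrics.
cv_run <- function(fold_feats, labels, fold, model_id, seed, type = "class") {
  k <- max(fold)
  n <- length(labels)
  oof <- rep(NA_real_, n)
  per_fold <- matrix(NA_real_, k, 4,
                     dimnames = list(NULL, c("accuracy", "f1", "precision", "recall")))
  for (f in seq_len(k)) {
    tr <- fold != f
    if (length(unique(labels[tr])) < 2) {
      stop("training fold ", f, " is single-class; use stratified folds or another seed")
    }
    fit <- fit_model(model_id, fold_feats[[f]]$train, labels[tr],
                     seed = seed + f, probability = (type == "prob"))
    pred <- predict_model(fit, fold_feats[[f]]$test, type = type)
    oof[!tr] <- pred
    if (type == "class") {
      per_fold[f, ] <- classification_metrics(labels[!tr], pred)
    } else {
      per_fold[f, ] <- classification_metrics(labels[!tr], as.integer(pred >= 0.5))
    }
  }
  pooled <- classification_metrics(labels, if (type == "class") oof else as.integer(oof >= 0.5))
  structure(list(model = model_id,
                 pooled = pooled,
                 per_fold = as.data.frame(per_fold),
                 oof = oof, fold = fold, seed = seed),
            class = "cv_result")
}

#' @exportS3Method print cv_result
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %s: accuracy %.4f, F1 %.4f, precision %.4f, recall %.4f (%d folds)\n",
              x$model, x$pooled["accuracy"], x$pooled["f1"],
              x$pooled["precision"], x$pooled["recall"], max(x$fold)))
  invisible(x)
}

#' Cross-validate one model on a feature block
#'
#' Stratified k-fold evaluation with metrics computed on the pooled
#' out-of-fold predictions (positive class = suicidal ideation).
#'
#' @param features a `feature_block` or numeric matrix
#' @param labels integer 0/1 labels
#' @param model_id a [model_zoo()] id
#' @param folds number of folds (default 5)
#' @param seed integer seed driving fold assignment and stochastic learners
#' @return a `cv_result` with `pooled` metrics, `per_fold` metrics, the
#'   out-of-fold predictions and the fold assignment
#' @export
evaluate_cv <- function(features, labels, model_id, folds = 5L, seed = 1L) {
  x <- if (inherits(features, "feature_block")) features$matrix else as.matrix(features)
  labels <- as.integer(labels)
  if (nrow(x) != length(labels)) stop("features and labels length mismatch")
  fold <- stratified_folds(labels, folds, seed)
  cv_run(block_fold_features(x, fold), labels, fold, model_id, seed)
}

#' Pick the best zoo model for a feature set
#'
#' Every model sees identical stratified folds. The winner has the highest
#' pooled accuracy; ties break by pooled F1, then by zoo order.
#'
#' @param features a `feature_block` or numeric matrix, OR a
#'   `combination_recipe` (then `blocks` must be given and any `-fs`
#'   selection is refit inside each training fold)
#' @param labels integer 0/1 labels
#' @param zoo character vector of model ids (default the full 12-model zoo)
#' @param folds,seed as in [evaluate_cv()]
#' @param blocks named list of raw family `feature_block`s (recipe input)
#' @param in_fold_selection refit `-fs` selectors inside each training fold
#'   (default TRUE; FALSE reproduces whole-data selection)
#' @return list with `best` (model id), `result` (its `cv_result`) and
#'   `leaderboard` (data.frame over the whole zoo)
#' @export
select_best <- function(features, labels, zoo = model_zoo(), folds = 5L,
                        seed = 1L, blocks = NULL, in_fold_selection = TRUE) {
  labels <- as.integer(labels)
  fold <- stratified_folds(labels, folds, seed)
  if (inherits(features, "combination_recipe")) {
    if (is.null(blocks)) stop("recipe evaluation needs the raw family blocks")
    fold_feats <- recipe_fold_features(features, blocks, labels, fold,
                                       in_fold_selection)
  } else {
    x <- if (inherits(features, "feature_block")) features$matrix else as.matrix(features)
    fold_feats <- block_fold_features(x, fold)
  }
  results <- lapply(zoo, function(id) cv_run(fold_feats, labels, fold, id, seed))
  acc <- vapply(results, function(r) r$pooled["accuracy"], 0)
  f1 <- vapply(results, function(r) r$pooled["f1"], 0)
  ord <- order(-acc, -f1, seq_along(zoo))
  best_i <- ord[1]
  leaderboard <- data.frame(model = zoo,
                            accuracy = acc, f1 = f1,
                            precision = vapply(results, function(r) r$pooled["precision"], 0),
                            recall = vapply(results, function(r) r$pooled["recall"], 0),
                            stringsAsFactors = FALSE)
  list(best = zoo[best_i], result = results[[best_i]], leaderboard = leaderboard)
}
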