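# Stacked feature-fusion ensemble: one base classifier per feature-set
# recipe, out-of-fold probability meta-features, logistic meta-classifier.

#' Construct an ensemble specification
#'
#' A feature set is one combination recipe; each set feeds its own base
#' classifier, and a logistic regression stacks the base classifiers'
#' out-of-fold probabilities. Together the feature sets must cover all three
#' families (`BSC`, `RFS`, `WEC`) so no information channel is dropped, and
#' at least two sets are required for stacking to be meaningful.
#'
#' @param feature_sets list of `combination_recipe`s
#' @param base_models optional character vector of [model_zoo()] ids, one per
#'   feature set; chosen by [select_best()] during fitting when `NULL`
#' @param folds folds used to build meta-features (default 5)
#' @param seed integer seed
#' @return an object of class `ensemble_spec`
#' @export
ensemble_spec <- function(feature_sets, base_models = NULL, folds = 5L, seed = 1L) {
  if (length(feature_sets) < 2) stop("an ensemble needs at least 2 feature sets")
  for (fs in feature_sets) {
    if (!inherits(fs, "combination_recipe")) stop("feature_sets must be combination_recipes")
  }
  covered <- unique(unlist(lapply(feature_sets, `[[`, "blocks")))
  missing <- setdiff(c("BSC", "RFS", "WEC"), covered)
  if (length(missing) > 0) {
    stop("feature sets do not cover all families; missing: ",
         paste(missing, collapse = ", "))
  }
  if (!is.null(base_models)) {
    if (length(base_models) != length(feature_sets)) {
      stop("base_models must have one id per feature set")
    }
    stopifnot(all(base_models %in% model_zoo()))
  }
  label <- paste(vapply(feature_sets, `[[`, "", "label"), collapse = " / ")
  structure(list(feature_sets = feature_sets, base_models = base_models,
                 folds = as.integer(folds), seed = as.integer(seed),
                 label = label),
            class = "ensemble_spec")
}

#' @exportS3Method print ensemble_spec
print.ensemble_spec <- function(x, ...) {
  cat(sprintf("<ensemble_spec> %s  (base: %s)\n", x$label,
              if (is.null(x$base_models)) "auto" else paste(x$base_models, collapse = ", ")))
  invisible(x)
}

#' Choose base classifiers for an ensemble by cross-validation
#'
#' Runs [select_best()] over the zoo for every feature set and returns the
#' spec with `base_models` filled in (plus the leaderboards).
#'
#' @param spec an [ensemble_spec()]
#' @param blocks named list of raw family `feature_block`s
#' @param labels integer 0/1 labels
#' @param zoo candidate model ids
#' @param in_fold_selection refit `-fs` selectors inside CV training folds
#' @return the spec, with `base_models` set and `leaderboards` attached
#' @export
choose_base_models <- function(spec, blocks, labels, zoo = model_zoo(),
                               in_fold_selection = TRUE) {
  picks <- lapply(spec$feature_sets, function(recipe) {
    select_best(recipe, labels, zoo = zoo, folds = spec$folds, seed = spec$seed,
                blocks = blocks, in_fold_selection = in_fold_selection)
  })
  spec$base_models <- vapply(picks, `[[`, "", "best")
  spec$leaderboards <- lapply(picks, `[[`, "leaderboard")
  spec
}

#' Out-of-fold meta-feature matrix
#'
#' Column s holds the out-of-fold positive-class probability of feature set
#' s's base classifier: every entry is predicted by a model whose training
#' folds exclude that row, so no label information leaks into the
#' meta-features.
#'
#' @param spec an [ensemble_spec()] with `base_models` set
#' @param blocks named list of raw family `feature_block`s
#' @param labels integer 0/1 labels
#' @param fold optional externally fixed fold assignment
#' @param in_fold_selection refit `-fs` selectors per training fold
#' @return numeric matrix (n x number of feature sets), columns named by
#'   recipe label
#' @export
build_meta_features <- function(spec, blocks, labels, fold = NULL,
                                in_fold_selection = TRUE) {
  if (is.null(spec$base_models)) {
    stop("spec has no base models; run choose_base_models() first")
  }
  labels <- as.integer(labels)
  if (is.null(fold)) fold <- stratified_folds(labels, spec$folds, spec$seed)
  k <- max(fold)
  meta <- matrix(NA_real_, length(labels), length(spec$feature_sets))
  colnames(meta) <- vapply(spec$feature_sets, `[[`, "", "label")
  for (s in seq_along(spec$feature_sets)) {
    fold_feats <- recipe_fold_features(spec$feature_sets[[s]], blocks, labels,
                                       fold, in_fold_selection)
    for (f in seq_len(k)) {
      tr <- fold != f
      fit <- fit_model(spec$base_models[s], fold_feats[[f]]$train, labels[tr],
                       seed = spec$seed + f, probability = TRUE)
      meta[!tr, s] <- predict_model(fit, fold_feats[[f]]$test, type = "prob")
    }
  }
  meta
}

#' Fit the feature-fusion stacked ensemble
#'
#' Builds the out-of-fold meta-feature matrix, fits the logistic
#' meta-classifier on it (L2 penalty, intercept included), then refits each
#' base classifier on all training data (with full-data feature selection)
#' for deployment.
#'
#' @param spec an [ensemble_spec()]; base models are chosen by
#'   [choose_base_models()] when not already set
#' @param blocks named list of raw family `feature_block`s
#' @param labels integer 0/1 labels
#' @param zoo candidate ids for base-model selection
#' @param in_fold_selection refit `-fs` selectors per training fold while
#'   building meta-features
#' @return an object of class `sf_fusion`
#' @export
fit_fusion <- function(spec, blocks, labels, zoo = model_zoo(),
                       in_fold_selection = TRUE) {
  labels <- as.integer(labels)
  if (is.null(spec$base_models)) {
    spec <- choose_base_models(spec, blocks, labels, zoo, in_fold_selection)
  }
  meta <- build_meta_features(spec, blocks, labels,
                              in_fold_selection = in_fold_selection)
  meta_fit <- fit_logistic(meta, labels, alpha = 0)
  base_fits <- lapply(seq_along(spec$feature_sets), function(s) {
    feats <- apply_recipe(spec$feature_sets[[s]], blocks, labels)
    fit <- fit_model(spec$base_models[s], feats$matrix, labels,
                     seed = spec$seed, probability = TRUE)
    list(fit = fit, kept = colnames(feats$matrix))
  })
  structure(list(spec = spec, meta_fit = meta_fit, base_fits = base_fits,
                 meta = meta, labels = labels),
            class = "sf_fusion")
}

#' Predict with a fitted fusion ensemble
#' @param object an `sf_fusion`
#' @param blocks named list of family `feature_block`s for the new posts
#' @param type `"class"` or `"prob"`
#' @param ... unused
#' @return numeric vector of labels or probabilities
#' @export
predict.sf_fusion <- function(object, blocks, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  full <- cbind_blocks(blocks)
  meta_new <- vapply(object$base_fits, function(b) {
    predict_model(b$fit, full$matrix[, b$kept, drop = FALSE], type = "prob")
  }, numeric(nrow(full$matrix)))
  if (is.null(dim(meta_new))) meta_new <- matrix(meta_new, nrow = 1)
  colnames(meta_new) <- vapply(object$spec$feature_sets, `[[`, "", "label")
  p <- predict_logistic(object$meta_fit, meta_new)
  if (type == "prob") p else as.integer(p >= 0.5)
}

#' Nested cross-validated evaluation of a fusion ensemble
#'
#' Wraps the whole fit (meta-feature construction, meta-classifier, base
#' refits) in an outer stratified k-fold loop, so reported metrics come from
#' posts the fitted ensemble never saw.
#'
#' @param spec an [ensemble_spec()] (base models fixed beforehand keeps the
#'   outer loop cheap; left `NULL` they are re-chosen in every outer fold)
#' @param blocks named list of raw family `feature_block`s
#' @param labels integer 0/1 labels
#' @param outer_folds outer folds (default 5)
#' @param seed integer seed for the outer split
#' @param zoo candidate ids when base models are re-chosen
#' @param in_fold_selection refit `-fs` selectors inside the inner
#'   meta-feature folds. The outer split already guards the reported metric
#'   against leakage, so `FALSE` (select once per outer training set) is a
#'   legitimate cheaper choice that only affects meta-classifier calibration
#' @return a `cv_result` (model id = spec label)
#' @export
evaluate_fusion_cv <- function(spec, blocks, labels, outer_folds = 5L,
                               seed = 1L, zoo = model_zoo(),
                               in_fold_selection = TRUE) {
  labels <- as.integer(labels)
  fold <- stratified_folds(labels, outer_folds, seed + 1000L)
  n <- length(labels)
  oof <- rep(NA_real_, n)
  per_fold <- matrix(NA_real_, outer_folds, 4,
                     dimnames = list(NULL, c("accuracy", "f1", "precision", "recall")))
  for (f in seq_len(outer_folds)) {
    tr <- fold != f
    blocks_tr <- lapply(blocks, function(b) {
      feature_block(b$matrix[tr, , drop = FALSE], b$block, b$row_ids[tr])
    })
    blocks_te <- lapply(blocks, function(b) {
      feature_block(b$matrix[!tr, , drop = FALSE], b$block, b$row_ids[!tr])
    })
    fit <- fit_fusion(spec, blocks_tr, labels[tr], zoo = zoo,
                      in_fold_selection = in_fold_selection)
    pred <- predict(fit, blocks_te, type = "class")
    oof[!tr] <- pred
    per_fold[f, ] <- classification_metrics(labels[!tr], pred)
  }
  structure(list(model = spec$label,
                 pooled = classification_metrics(labels, oof),
                 per_fold = as.data.frame(per_fold),
                 oof = oof, fold = fold, seed = seed),
            class = "cv_result")
}

#' The 11 reference feature-set configurations
#'
#' Enumerates the fusion configurations compared in the study design: for
#' each way of pairing two families against the third, the direct,
#' select-then-combine and combine-then-select variants, plus the two
#' all-singleton configurations (with and without per-family selection).
#' Includes the headline configuration \{(BSC + RFS)-fs, WEC-fs\}.
#'
#' @param selection a [selection_config()] shared by all `-fs` recipes
#' @param folds,seed passed to each [ensemble_spec()]
#' @return list of 11 `ensemble_spec`s
#' @export
enumerate_paper_feature_sets <- function(selection = selection_config(),
                                         folds = 5L, seed = 1L) {
  r <- function(blocks, mode) combination_recipe(blocks, mode, selection)
  pairings <- list(c("BSC", "RFS"), c("BSC", "WEC"), c("RFS", "WEC"))
  specs <- list()
  for (pair in pairings) {
    rest <- setdiff(c("BSC", "RFS", "WEC"), pair)
    specs <- c(specs, list(
      ensemble_spec(list(r(pair, "direct"), r(rest, "direct")),
                    folds = folds, seed = seed),
      ensemble_spec(list(r(pair, "select-then-combine"),
                         r(rest, "select-then-combine")),
                    folds = folds, seed = seed),
      ensemble_spec(list(r(pair, "combine-then-select"),
                         r(rest, "select-then-combine")),
                    folds = folds, seed = seed)
    ))
  }
  specs <- c(specs, list(
    ensemble_spec(list(r("BSC", "direct"), r("RFS", "direct"), r("WEC", "direct")),
                  folds = folds, seed = seed),
    ensemble_spec(list(r("BSC", "select-then-combine"),
                       r("RFS", "select-then-combine"),
                       r("WEC", "select-then-combine")),
                  folds = folds, seed = seed)
  ))
  specs
}
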