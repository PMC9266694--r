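# Reference ensemble baselines evaluated under the same stratified 5-fold
# protocol as the fusion model: random forests (gini/entropy), gradient
# boosting (generic, tree-boosted and linear-boosted), AdaBoost and bagging
# over decision trees, classic stacking, and a majority-class dummy.

BASELINE_IDS <- c("RF-entropy", "RF-gini", "XGB-gbtree", "XGB-gblinear",
                  "AdaBoost-tree", "Bagging-tree", "GradientBoosting",
                  "Stacking", "DummyMajority")

#' Baseline identifiers
#' @return character vector of the 9 baseline configurations
#' @export
baseline_ids <- function() BASELINE_IDS

# --- AdaBoost (SAMME over depth-1 rpart stumps, 50 rounds) ----------------
fit_adaboost <- function(x, y, n_rounds = 50L, max_depth = 1L) {
  n <- length(y)
  w <- rep(1 / n, n)
  df <- as.data.frame(x)
  names(df) <- sprintf("V%d", seq_len(ncol(x)))
  df$.y <- factor(y, levels = 0:1)
  stumps <- list(); alphas <- numeric(0)
  for (m in seq_len(n_rounds)) {
    fit <- rpart::rpart(.y ~ ., data = df, weights = w, method = "class",
                        control = rpart::rpart.control(maxdepth = max_depth,
                                                       cp = 0, minsplit = 2,
                                                       xval = 0))
    pred <- as.integer(as.character(predict(fit, df, type = "class")))
    err <- sum(w * (pred != y))
    if (err <= 1e-10) { stumps[[m]] <- fit; alphas[m] <- 10; break }
    if (err >= 0.5) break
    alpha <- 0.5 * log((1 - err) / err)
    stumps[[m]] <- fit; alphas[m] <- alpha
    w <- w * exp(alpha * ifelse(pred != y, 1, -1))
    w <- w / sum(w)
  }
  if (length(stumps) == 0) { # no useful learner: fall back to prior
    return(list(stumps = list(), alphas = numeric(0), prior = mean(y)))
  }
  list(stumps = stumps, alphas = alphas, prior = mean(y))
}

predict_adaboost <- function(fit, x) {
  if (length(fit$stumps) == 0) return(rep(as.integer(fit$prior >= 0.5), nrow(x)))
  df <- as.data.frame(x)
  names(df) <- sprintf("V%d", seq_len(ncol(x)))
  score <- rep(0, nrow(x))
  for (m in seq_along(fit$stumps)) {
    pred <- as.integer(as.character(predict(fit$stumps[[m]], df, type = "class")))
    score <- score + fit$alphas[m] * (2 * pred - 1)
  }
  as.integer(score >= 0)
}

# --- xgboost wrappers ------------------------------------------------------
fit_xgb <- function(x, y, booster, eta, max_depth, nrounds, seed) {
  if (booster == "gbtree") {
    xgboost::xgboost(x, factor(y, levels = 0:1),
                     objective = "binary:logistic", booster = "gbtree",
                     nrounds = nrounds, learning_rate = eta,
                     max_depth = max_depth, nthreads = 1, seed = seed,
                     verbosity = 0)
  } else {
    xgboost::xgboost(x, factor(y, levels = 0:1),
                     objective = "binary:logistic", booster = "gblinear",
                     nrounds = nrounds, nthreads = 1, seed = seed,
                     verbosity = 0)
  }
}

# --- classic stacking ------------------------------------------------------
# All base models see the full feature matrix; a logistic meta-classifier is
# trained on their out-of-fold probabilities (inner folds nested inside the
# training data).
fit_stacking <- function(x, y, base_ids, folds = 5L, seed = 1L) {
  inner <- stratified_folds(y, folds, seed + 17L)
  meta <- matrix(NA_real_, length(y), length(base_ids))
  for (s in seq_along(base_ids)) {
    for (f in seq_len(folds)) {
      tr <- inner != f
      fit <- fit_model(base_ids[s], x[tr, , drop = FALSE], y[tr],
                       seed = seed + f, probability = TRUE)
      meta[!tr, s] <- predict_model(fit, x[!tr, , drop = FALSE], type = "prob")
    }
  }
  colnames(meta) <- base_ids
  meta_fit <- fit_logistic(meta, y, alpha = 0)
  base_fits <- lapply(base_ids, function(id) {
    fit_model(id, x, y, seed = seed, probability = TRUE)
  })
  list(meta_fit = meta_fit, base_fits = base_fits, base_ids = base_ids)
}

predict_stacking <- function(fit, x) {
  meta <- vapply(fit$base_fits, function(b) predict_model(b, x, type = "prob"),
                 numeric(nrow(x)))
  if (is.null(dim(meta))) meta <- matrix(meta, nrow = 1)
  colnames(meta) <- fit$base_ids
  as.integer(predict_logistic(fit$meta_fit, meta) >= 0.5)
}

baseline_fit_predict <- function(id, x_tr, y_tr, x_te, seed, stacking_bases) {
  switch(id,
    "RF-entropy" = predict(sf_forest(x_tr, y_tr, n_trees = 100L,
                                     criterion = "entropy", split = "best",
                                     bootstrap = TRUE, seed = seed),
                           x_te, type = "class"),
    "RF-gini" = predict(sf_forest(x_tr, y_tr, n_trees = 100L,
                                  criterion = "gini", split = "best",
                                  bootstrap = TRUE, seed = seed),
                        x_te, type = "class"),
    "XGB-gbtree" = as.integer(predict(
      fit_xgb(x_tr, y_tr, "gbtree", eta = 0.3, max_depth = 6, nrounds = 100,
              seed = seed), x_te) >= 0.5),
    "XGB-gblinear" = as.integer(predict(
      fit_xgb(x_tr, y_tr, "gblinear", eta = NA, max_depth = NA, nrounds = 100,
              seed = seed), x_te) >= 0.5),
    "AdaBoost-tree" = predict_adaboost(fit_adaboost(x_tr, y_tr), x_te),
    "Bagging-tree" = predict(sf_forest(x_tr, y_tr, n_trees = 10L,
                                       criterion = "gini", split = "best",
                                       bootstrap = TRUE, mtry = ncol(x_tr),
                                       seed = seed),
                             x_te, type = "class"),
    "GradientBoosting" = as.integer(predict(
      fit_xgb(x_tr, y_tr, "gbtree", eta = 0.1, max_depth = 3, nrounds = 100,
              seed = seed), x_te) >= 0.5),
    "Stacking" = predict_stacking(
      fit_stacking(x_tr, y_tr, stacking_bases, seed = seed), x_te),
    "DummyMajority" = rep(as.integer(mean(y_tr) >= 0.5), nrow(x_te)),
    stop("unknown baseline id: ", id)
  )
}

#' Evaluate the reference ensemble baselines
#'
#' Runs the 9 baseline configurations over identical stratified folds
#' (paired comparison) on one feature matrix and returns pooled out-of-fold
#' metrics per baseline.
#'
#' @param features a `feature_block` or numeric matrix
#' @param labels integer 0/1 labels
#' @param seed integer seed (drives folds and stochastic learners)
#' @param folds number of folds (default 5)
#' @param ids subset of [baseline_ids()] to run
#' @param stacking_bases base-model ids for the classic-stacking baseline;
#'   conventionally the previously selected per-feature best models
#' @return list of `cv_result`s, one per baseline, named by id
#' @export
run_baselines <- function(features, labels, seed = 1L, folds = 5L,
                          ids = baseline_ids(),
                          stacking_bases = c("SVM-l", "Log-l1", "Log-l2",
                                             "NB", "ET-g", "ET-e")) {
  x <- if (inherits(features, "feature_block")) features$matrix else as.matrix(features)
  storage.mode(x) <- "double"
  labels <- as.integer(labels)
  fold <- stratified_folds(labels, folds, seed)
  results <- lapply(ids, function(id) {
    oof <- rep(NA_real_, length(labels))
    per_fold <- matrix(NA_real_, folds, 4,
                       dimnames = list(NULL, c("accuracy", "f1", "precision", "recall")))
    for (f in seq_len(folds)) {
      tr <- fold != f
      pred <- withr::with_seed(seed + f,
        baseline_fit_predict(id, x[tr, , drop = FALSE], labels[tr],
                             x[!tr, , drop = FALSE], seed + f, stacking_bases))
      oof[!tr] <- pred
      per_fold[f, ] <- classification_metrics(labels[!tr], pred)
    }
    structure(list(model = id,
                   pooled = classification_metrics(labels, oof),
                   per_fold = as.data.frame(per_fold),
                   oof = oof, fold = fold, seed = seed),
              class = "cv_result")
  })
  names(results) <- ids
  results
}
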