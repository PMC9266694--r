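#' Fit a randomized tree ensemble
#'
#' A compact forest learner for binary classification supporting the
#' gini/entropy impurity contrast and both split-search styles: exhaustive
#' best-split search (random forest / bagging style) and random-threshold
#' search (extremely randomized trees). Feature importances are
#' mean-decrease-in-impurity, normalized to sum to 1.
#'
#' @param x numeric feature matrix
#' @param y integer 0/1 labels
#' @param n_trees number of trees
#' @param mtry features tried per split; default `floor(sqrt(ncol(x)))`
#' @param criterion `"gini"` or `"entropy"`
#' @param split `"random"` (extremely randomized) or `"best"`
#' @param bootstrap draw a bootstrap sample per tree
#' @param min_split minimum node size eligible for splitting
#' @param max_depth depth cap
#' @param seed integer seed (mandatory; the forest is deterministic given it)
#' @return an object of class `sf_forest`
#' @export
sf_forest <- function(x, y, n_trees = 100L, mtry = NULL,
                      criterion = c("gini", "entropy"),
                      split = c("random", "best"),
                      bootstrap = FALSE, min_split = 2L, max_depth = 60L,
                      seed) {
  criterion <- match.arg(criterion)
  split <- match.arg(split)
  if (missing(seed)) stop("seed is mandatory")
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- as.integer(y)
  if (length(unique(y)) < 2) stop("need both classes to fit a forest")
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(x))))
  mtry <- min(as.integer(mtry), ncol(x))
  fit <- .forest_fit(x, y, as.integer(n_trees), mtry, as.integer(min_split),
                     as.integer(max_depth), criterion == "entropy",
                     split == "random", bootstrap, as.integer(seed))
  imp <- fit$importance
  if (sum(imp) > 0) imp <- imp / sum(imp)
  names(imp) <- colnames(x)
  structure(list(trees = fit$trees, importance = imp,
                 n_features = ncol(x), feature_names = colnames(x),
                 criterion = criterion, split = split, seed = seed),
            class = "sf_forest")
}

#' Predict from a fitted forest
#' @param object an `sf_forest`
#' @param newdata numeric matrix with the training columns
#' @param type `"prob"` for class-1 probability, `"class"` for 0/1 labels
#' @param ... unused
#' @return numeric or integer vector
#' @export
predict.sf_forest <- function(object, newdata, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  if (!is.null(object$feature_names)) {
    newdata <- newdata[, object$feature_names, drop = FALSE]
  }
  storage.mode(newdata) <- "double"
  p <- .forest_predict(object$trees, newdata)
  if (type == "prob") p else as.integer(p >= 0.5)
}
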