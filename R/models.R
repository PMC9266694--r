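# The classifier zoo: four SVM kernels, naive Bayes, KNN, L1/L2 logistic
# regression, gini/entropy decision trees and gini/entropy extremely
# randomized trees, behind one fit/predict interface.

ZOO_IDS <- c("SVM-l", "SVM-rbf", "SVM-poly", "SVM-sig", "NB", "KNN",
             "Log-l1", "Log-l2", "DT-g", "DT-e", "ET-g", "ET-e")

#' The default classifier zoo
#'
#' Returns the 12 model identifiers evaluated per feature set: SVMs with
#' linear, RBF, polynomial and sigmoid kernels, Gaussian naive Bayes,
#' 5-nearest-neighbors, logistic regression with L1 and L2 penalties, and
#' decision trees / extremely randomized trees each under the gini and
#' entropy impurity criteria. All models run at default parameters.
#'
#' @return character vector of model ids
#' @export
model_zoo <- function() ZOO_IDS

#' Fit one zoo model
#'
#' @param id a model id from [model_zoo()]
#' @param x numeric feature matrix
#' @param y integer 0/1 labels
#' @param seed integer seed (stochastic learners and probability calibration)
#' @param probability also fit whatever is needed to emit class-1
#'   probabilities (slower for SVMs; off by default)
#' @return an object of class `sf_model`
#' @export
fit_model <- function(id, x, y, seed = 1L, probability = FALSE) {
  if (!id %in% ZOO_IDS) stop("unknown model id: ", id)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- as.integer(y)
  if (length(unique(y)) < 2) stop("training labels contain a single class")
  fit <- withr::with_seed(seed, switch(id,
    "SVM-l" = e1071::svm(x, factor(y, levels = 0:1), kernel = "linear",
                         scale = FALSE, probability = probability),
    "SVM-rbf" = e1071::svm(x, factor(y, levels = 0:1), kernel = "radial",
                           scale = FALSE, probability = probability),
    "SVM-poly" = e1071::svm(x, factor(y, levels = 0:1), kernel = "polynomial",
                            scale = FALSE, probability = probability),
    "SVM-sig" = e1071::svm(x, factor(y, levels = 0:1), kernel = "sigmoid",
                           scale = FALSE, probability = probability),
    "NB" = e1071::naiveBayes(x, factor(y, levels = 0:1)),
    # the tie column is ~1e-6 in scale: far below any real distance contrast,
    # it only breaks the exact-duplicate-row ties that choke kNN on sparse
    # rate features
    "KNN" = list(train = cbind(x, .tie = seq_along(y) * (1e-6 / length(y))),
                 y = y, k = 5L),
    "Log-l1" = fit_logistic(x, y, alpha = 1),
    "Log-l2" = fit_logistic(x, y, alpha = 0),
    "DT-g" = fit_rpart(x, y, "gini"),
    "DT-e" = fit_rpart(x, y, "information"),
    "ET-g" = sf_forest(x, y, n_trees = 100L, criterion = "gini",
                       split = "random", seed = seed),
    "ET-e" = sf_forest(x, y, n_trees = 100L, criterion = "entropy",
                       split = "random", seed = seed)
  ))
  structure(list(id = id, fit = fit, features = colnames(x),
                 probability = probability, seed = seed),
            class = "sf_model")
}

# Penalized logistic regression at a unit-strength penalty (lambda = 1/n).
# glmnet is fit along a decreasing lambda path down to the target value --
# warm starts make this fast and reliable where a single small lambda
# does not converge.
fit_logistic <- function(x, y, alpha) {
  s <- 1 / length(y)
  lambda <- exp(seq(log(0.5), log(s), length.out = 30))
  fit <- glmnet::glmnet(x, y, family = "binomial", alpha = alpha,
                        lambda = lambda)
  list(fit = fit, s = s)
}

predict_logistic <- function(model, x) {
  as.numeric(predict(model$fit, x, s = model$s, type = "response"))
}

# rpart with safe internal column names; cp = 0 / minsplit = 2 grows the
# full tree, emulating default unpruned CART
fit_rpart <- function(x, y, split) {
  df <- as.data.frame(x)
  names(df) <- sprintf("V%d", seq_len(ncol(x)))
  df$.y <- factor(y, levels = 0:1)
  fit <- rpart::rpart(.y ~ ., data = df, method = "class",
                      parms = list(split = split),
                      control = rpart::rpart.control(cp = 0, minsplit = 2,
                                                     xval = 0, maxdepth = 30))
  list(fit = fit, n_cols = ncol(x))
}

#' Predict from a fitted zoo model
#'
#' @param model an `sf_model`
#' @param x numeric matrix with the training columns
#' @param type `"class"` (0/1) or `"prob"` (class-1 probability)
#' @return numeric vector
#' @export
predict_model <- function(model, x, type = c("class", "prob")) {
  type <- match.arg(type)
  x <- as.matrix(x)
  if (!is.null(model$features)) x <- x[, model$features, drop = FALSE]
  storage.mode(x) <- "double"
  id <- model$id
  if (id %in% c("SVM-l", "SVM-rbf", "SVM-poly", "SVM-sig")) {
    if (type == "prob") {
      if (!model$probability) stop("SVM was fitted without probability = TRUE")
      pr <- predict(model$fit, x, probability = TRUE)
      return(unname(attr(pr, "probabilities")[, "1"]))
    }
    return(as.integer(as.character(predict(model$fit, x))))
  }
  if (id == "NB") {
    p <- predict(model$fit, x, type = "raw")[, "1"]
    return(if (type == "prob") unname(p) else as.integer(p >= 0.5))
  }
  if (id == "KNN") {
    xq <- cbind(x, .tie = 0)
    pred <- withr::with_seed(model$seed,
      class::knn(model$fit$train, xq, factor(model$fit$y, levels = 0:1),
                 k = model$fit$k, prob = TRUE, use.all = FALSE))
    win <- attr(pred, "prob")
    lab <- as.integer(as.character(pred))
    p1 <- ifelse(lab == 1L, win, 1 - win)
    return(if (type == "prob") p1 else lab)
  }
  if (id %in% c("Log-l1", "Log-l2")) {
    p <- predict_logistic(model$fit, x)
    return(if (type == "prob") p else as.integer(p >= 0.5))
  }
  if (id %in% c("DT-g", "DT-e")) {
    df <- as.data.frame(x)
    names(df) <- sprintf("V%d", seq_len(ncol(x)))
    p <- predict(model$fit$fit, df, type = "prob")[, "1"]
    return(if (type == "prob") unname(p) else as.integer(p >= 0.5))
  }
  if (id %in% c("ET-g", "ET-e")) {
    p <- predict(model$fit, x, type = "prob")
    return(if (type == "prob") p else as.integer(p >= 0.5))
  }
  stop("unreachable")
}
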