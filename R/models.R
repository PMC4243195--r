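# Six posterior-emitting classifiers behind one train/predict surface.
# Margin classifiers (the two SVMs) are sigmoid-calibrated (Platt); the
# random forest posterior is the fraction of votes from its 100 trees.

MODEL_KINDS <- c("logistic_regression", "fisher_lda", "naive_bayes",
                 "linear_svm", "gaussian_svm", "random_forest")

#' Train a site- or UTR-level classifier
#'
#' @param kind one of `"logistic_regression"`, `"fisher_lda"`,
#'   `"naive_bayes"`, `"linear_svm"`, `"gaussian_svm"`,
#'   `"random_forest"`.
#' @param features data.frame/matrix of numeric features.
#' @param labels factor or character with levels `negative`/`positive`;
#'   both classes must be present.
#' @param hyperparams optional list: `cost`, `gamma` (SVMs), `ntree`
#'   (forest, default 100).
#' @param rng_seed integer seed; training is deterministic given it.
#' @return Object of class `trained_model` carrying the fit, the feature
#'   names used (zero-variance columns are dropped) and the seed.
#' @export
train_model <- function(kind, features, labels, hyperparams = list(),
                        rng_seed = 1L) {
  kind <- match.arg(kind, MODEL_KINDS)
  x <- as.data.frame(features)
  stopifnot(all(vapply(x, is.numeric, logical(1))))
  if (any(!is.finite(as.matrix(x)))) stop("non-finite feature values")
  y <- factor(as.character(labels), levels = c("negative", "positive"))
  if (any(is.na(y))) stop("labels must be 'negative'/'positive'")
  if (nlevels(droplevels(y)) < 2L)
    stop("training data contain a single class")
  keep <- vapply(x, function(v) stats::var(v) > 0, logical(1))
  if (!any(keep)) stop("all features are constant")
  x <- x[, keep, drop = FALSE]
  fit <- with_seed(rng_seed, switch(
    kind,
    logistic_regression = suppressWarnings(
      glm(y ~ ., data = cbind(x, y = y), family = binomial())),
    fisher_lda = MASS::lda(x, grouping = y),
    naive_bayes = e1071::naiveBayes(x, y),
    linear_svm = e1071::svm(
      x, y, kernel = "linear", probability = TRUE, scale = TRUE,
      cost = hyperparams$cost %||% 1),
    gaussian_svm = e1071::svm(
      x, y, kernel = "radial", probability = TRUE, scale = TRUE,
      cost = hyperparams$cost %||% 1,
      gamma = hyperparams$gamma %||% (1 / ncol(x))),
    random_forest = randomForest::randomForest(
      x, y, ntree = hyperparams$ntree %||% 100L)))
  structure(list(kind = kind, fit = fit, feature_names = colnames(x),
                 hyperparams = hyperparams, rng_seed = rng_seed),
            class = "trained_model")
}

#' Posterior probabilities from a trained model
#'
#' @param model a [train_model()] result.
#' @param features data.frame containing at least the model's feature
#'   columns; a missing column is an error naming it.
#' @return Numeric vector of posterior probabilities of the positive
#'   class, in `[0, 1]`.
#' @export
predict_posterior <- function(model, features) {
  stopifnot(inherits(model, "trained_model"))
  x <- as.data.frame(features)
  miss <- setdiff(model$feature_names, names(x))
  if (length(miss))
    stop("missing feature(s): ", paste(miss, collapse = ", "))
  x <- x[, model$feature_names, drop = FALSE]
  p <- switch(
    model$kind,
    logistic_regression = as.numeric(
      predict(model$fit, newdata = x, type = "response")),
    fisher_lda = as.numeric(predict(model$fit, x)$posterior[, "positive"]),
    naive_bayes = as.numeric(
      predict(model$fit, x, type = "raw")[, "positive"]),
    linear_svm = ,
    gaussian_svm = {
      pr <- predict(model$fit, x, probability = TRUE)
      as.numeric(attr(pr, "probabilities")[, "positive"])
    },
    random_forest = as.numeric(
      predict(model$fit, x, type = "prob")[, "positive"]))
  pmin(1, pmax(0, p))
}

#' Grid selection of SVM hyperparameters by cross-validated AUC
#'
#' @param kind `"linear_svm"` or `"gaussian_svm"`.
#' @param features,labels training data.
#' @param costs,gammas candidate grids.
#' @param k folds.
#' @param rng_seed integer seed.
#' @return List with the winning `cost`, `gamma` and the grid of AUCs.
#' @export
tune_svm <- function(kind, features, labels, costs = c(0.1, 1, 10),
                     gammas = c(0.01, 0.1, 1), k = 5L, rng_seed = 1L) {
  kind <- match.arg(kind, c("linear_svm", "gaussian_svm"))
  if (kind == "linear_svm") gammas <- NA_real_
  grid <- expand.grid(cost = costs, gamma = gammas)
  grid$auc <- vapply(seq_len(nrow(grid)), function(i) {
    hp <- list(cost = grid$cost[i])
    if (!is.na(grid$gamma[i])) hp$gamma <- grid$gamma[i]
    rep <- crossvalidate(features, labels, k = k, kinds = kind,
                         hyperparams = hp, rng_seed = rng_seed)
    rep$metrics$auc[1]
  }, numeric(1))
  best <- which.max(grid$auc)
  list(cost = grid$cost[best],
       gamma = if (is.na(grid$gamma[best])) NULL else grid$gamma[best],
       grid = grid)
}

#' Save / load a model bundle
#'
#' The bundle is a versioned list (kind, fit, feature names, seed) written
#' with `saveRDS`.
#'
#' @param model a `trained_model`.
#' @param path file path.
#' @return `path` (save) or the restored `trained_model` (load).
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "trained_model"))
  saveRDS(list(format = "mirtarget-model", version = 1L, model = model),
          path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  b <- readRDS(path)
  if (!identical(b$format, "mirtarget-model"))
    stop("'", path, "' is not a model bundle")
  b$model
}
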