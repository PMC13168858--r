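#' Classifier specification
#'
#' Names one of the four supported model families and its hyperparameter
#' grid. The SVM family always projects onto principal components retaining
#' 95% of the variance before the RBF kernel machine. Default grids:
#' SVM cost {0.1, 1, 10} x kernel width {0.01, 0.1, 1}; decision tree
#' max depth {3, 5, 7, unlimited} x min leaf {1, 2, 4}; random forest trees
#' {100, 300} x max depth {unlimited, 5, 10}; boosted trees rounds
#' {100, 300} x depth {3, 5} x learning rate {0.05, 0.1}.
#'
#' @param family one of `"svm_rbf_pca"`, `"decision_tree"`,
#'   `"random_forest"`, `"xgboost"`.
#' @param grid data frame of hyperparameter combinations (one row per
#'   candidate); `NULL` uses the family default.
#' @param rng_seed integer seed threaded through stochastic fits.
#' @return list of class `model_spec`.
#' @export
model_spec <- function(family = c("random_forest", "decision_tree",
                                  "xgboost", "svm_rbf_pca"),
                       grid = NULL, rng_seed = NULL) {
  family <- match.arg(family)
  if (is.null(grid)) grid <- default_grid(family)
  structure(list(family = family, grid = grid, rng_seed = rng_seed),
            class = "model_spec")
}

default_grid <- function(family) {
  switch(family,
    svm_rbf_pca = expand.grid(cost = c(0.1, 1, 10),
                              gamma = c(0.01, 0.1, 1)),
    decision_tree = expand.grid(max_depth = c(3, 5, 7, Inf),
                                min_leaf = c(1, 2, 4)),
    random_forest = expand.grid(n_trees = c(100, 300),
                                max_depth = c(Inf, 5, 10)),
    xgboost = expand.grid(n_rounds = c(100, 300), depth = c(3, 5),
                          learning_rate = c(0.05, 0.1)))
}

# labels -> 0/1 with "deteriorated" (or the second factor level) positive
binary_outcome <- function(labels) {
  labels <- as.character(labels)
  positive <- if ("deteriorated" %in% labels) "deteriorated"
              else sort(unique(labels))[2]
  list(y = as.numeric(labels == positive), positive = positive)
}

#' Fit a classifier
#'
#' @param spec a [model_spec()].
#' @param params one row of the hyperparameter grid (list or 1-row data
#'   frame).
#' @param x numeric feature matrix or data frame (rows = samples).
#' @param labels two-class label vector; `"deteriorated"` is the positive
#'   class when present.
#' @param seed optional seed for stochastic fits.
#' @return fitted classifier of class `ocufatigue_model`.
#' @export
fit_classifier <- function(spec, params, x, labels, seed = NULL) {
  stopifnot(inherits(spec, "model_spec"))
  x <- as.matrix(x)
  out <- binary_outcome(labels)
  if (length(unique(out$y)) < 2) stop("single-class training input")
  params <- as.list(params)
  fit <- with_seed(seed, switch(spec$family,
    decision_tree = cart_fit(x, out$y, "class",
                             max_depth = params$max_depth %||% Inf,
                             min_leaf = params$min_leaf %||% 1L),
    random_forest = rf_fit(x, out$y,
                           n_trees = params$n_trees %||% 100L,
                           max_depth = params$max_depth %||% Inf,
                           min_leaf = params$min_leaf %||% 1L),
    xgboost = gbt_fit(x, out$y,
                      n_rounds = params$n_rounds %||% 100L,
                      depth = params$depth %||% 3L,
                      learning_rate = params$learning_rate %||% 0.1),
    svm_rbf_pca = svm_fit(x, out$y, cost = params$cost %||% 1,
                          gamma = params$gamma %||% NULL)))
  structure(list(family = spec$family, fit = fit, params = params,
                 feature_names = colnames(x), positive = out$positive),
            class = "ocufatigue_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Predict the positive-class probability
#'
#' @param model an `ocufatigue_model`.
#' @param newdata matrix or data frame with the training feature columns.
#' @return numeric vector of probabilities (for the SVM, a logistic
#'   squashing of the decision value, i.e. a pseudo-probability).
#' @export
predict_prob <- function(model, newdata) {
  stopifnot(inherits(model, "ocufatigue_model"))
  newdata <- as.data.frame(newdata)
  missing <- setdiff(model$feature_names, names(newdata))
  if (length(missing))
    stop("feature schema mismatch; missing: ", paste(missing, collapse = ", "))
  x <- as.matrix(newdata[, model$feature_names, drop = FALSE])
  switch(model$family,
         decision_tree = cart_predict(model$fit, x),
         random_forest = rf_predict(model$fit, x),
         xgboost = gbt_predict(model$fit, x),
         svm_rbf_pca = svm_predict(model$fit, x))
}

#' Rank features by ensemble importance
#'
#' Mean-decrease-in-impurity scores of a fitted tree ensemble (random
#' forest or boosted trees), normalised to sum to 1, in descending order.
#'
#' @param model an `ocufatigue_model` with a tree-ensemble family.
#' @param feature_names names to attach (defaults to training names).
#' @return data frame `feature`, `importance` sorted descending.
#' @export
rank_feature_importance <- function(model, feature_names = NULL) {
  stopifnot(inherits(model, "ocufatigue_model"))
  if (!model$family %in% c("random_forest", "xgboost"))
    stop("feature importance requires a tree-ensemble model, not ",
         model$family)
  imp <- model$fit$importance
  if (is.null(feature_names)) feature_names <- model$feature_names
  tot <- sum(imp)
  sc <- if (tot > 0) imp / tot else rep(1 / length(imp), length(imp))
  ord <- order(-sc)
  data.frame(feature = feature_names[ord], importance = unname(sc[ord]))
}
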