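# Evaluation protocol: stratified holdout, in-fold SMOTE + z-scoring,
# stratified five-fold grid search and cross-validation, holdout scoring.

#' Classification metrics
#'
#' Accuracy, F1 (positive class = deteriorated), balanced accuracy and
#' AUROC (rank-based, tie-aware). Balanced accuracy is `NA` when the truth
#' contains a single class; AUROC is `NA` in that case too.
#'
#' @param probs positive-class probabilities.
#' @param labels true labels.
#' @param threshold decision threshold on the probability.
#' @param positive positive class name.
#' @return named numeric `c(accuracy, f1, balanced_accuracy, auroc)`.
#' @export
classification_metrics <- function(probs, labels, threshold = 0.5,
                                   positive = "deteriorated") {
  truth <- as.character(labels) == positive
  pred <- probs >= threshold
  acc <- mean(pred == truth)
  tp <- sum(pred & truth); fp <- sum(pred & !truth); fn <- sum(!pred & truth)
  f1 <- if (2 * tp + fp + fn == 0) NA_real_ else 2 * tp / (2 * tp + fp + fn)
  if (!any(truth) || all(truth)) {
    bal <- NA_real_; auc <- NA_real_
  } else {
    sens <- tp / sum(truth)
    spec <- sum(!pred & !truth) / sum(!truth)
    bal <- (sens + spec) / 2
    auc <- auroc(probs, truth)
  }
  c(accuracy = acc, f1 = f1, balanced_accuracy = bal, auroc = auc)
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUROC with ties counted as half.
#'
#' @param scores numeric scores, higher = more positive.
#' @param truth logical (or coercible) positive indicator.
#' @return AUROC in `[0, 1]`, `NA` when only one class is present.
#' @export
auroc <- function(scores, truth) {
  truth <- as.logical(truth)
  n1 <- sum(truth); n0 <- sum(!truth)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[truth]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Stratified train/test split
#'
#' Samples `round(n_class * test_fraction)` test rows per class, preserving
#' class proportions within rounding; deterministic under `seed`.
#'
#' @param labels class labels.
#' @param test_fraction fraction held out.
#' @param seed integer seed.
#' @return list with integer `train` and `test` row indices.
#' @export
stratified_holdout_split <- function(labels, test_fraction = 0.2,
                                     seed = NULL) {
  labels <- as.character(labels)
  counts <- table(labels)
  if (test_fraction > 0 && any(counts < 2))
    stop("each class needs at least 2 samples")
  test <- integer(0)
  with_seed(seed, {
    for (cl in names(counts)) {
      idx <- which(labels == cl)
      k <- round(length(idx) * test_fraction)
      if (k > 0) test <- c(test, sample(idx, k))
    }
  })
  test <- sort(test)
  list(train = setdiff(seq_along(labels), test), test = test)
}

#' SMOTE oversampling of the minority class
#'
#' Synthetic minority samples are uniform interpolations between a minority
#' sample and one of its `k_neighbors` nearest minority neighbours
#' (Euclidean), generated until the classes are balanced. Originals are
#' preserved unchanged and the majority class is untouched. `k_neighbors`
#' is capped at (minority size - 1).
#'
#' @param features numeric matrix or data frame.
#' @param labels two-class label vector.
#' @param k_neighbors number of candidate neighbours.
#' @param seed integer seed.
#' @return list with `features` (matrix) and `labels`; synthetic rows are
#'   appended after the originals.
#' @export
smote_balance <- function(features, labels, k_neighbors = 5, seed = NULL) {
  x <- as.matrix(features)
  labels <- as.character(labels)
  counts <- table(labels)
  if (length(counts) < 2) stop("need two classes for SMOTE")
  if (min(counts) < 2) stop("minority class needs at least 2 samples")
  minority <- names(counts)[which.min(counts)]
  n_new <- max(counts) - min(counts)
  if (n_new == 0) return(list(features = x, labels = labels))
  mi <- which(labels == minority)
  xm <- x[mi, , drop = FALSE]
  k <- min(k_neighbors, length(mi) - 1L)
  d <- as.matrix(stats::dist(xm))
  diag(d) <- Inf
  nn <- t(apply(d, 1, function(row) order(row)[seq_len(k)]))
  synth <- with_seed(seed, {
    base_idx <- sample(rep_len(seq_along(mi), n_new))
    t(vapply(base_idx, function(i) {
      j <- nn[i, sample.int(k, 1)]
      u <- stats::runif(1)
      xm[i, ] + u * (xm[j, ] - xm[i, ])
    }, numeric(ncol(x))))
  })
  list(features = rbind(x, synth),
       labels = c(labels, rep(minority, n_new)))
}

#' Z-score standardisation with training statistics
#'
#' Per-feature mean and SD are estimated on the training features only and
#' applied to `apply_to`. Zero-SD features are centred and passed through
#' with a warning.
#'
#' @param train_features training matrix/data frame (>= 2 rows).
#' @param apply_to matrix to standardise (defaults to the training set).
#' @return standardised matrix with attributes `center` and `scale`.
#' @export
zscore_transform <- function(train_features, apply_to = train_features) {
  tr <- as.matrix(train_features)
  ap <- as.matrix(apply_to)
  mu <- colMeans(tr)
  sdv <- apply(tr, 2, stats::sd)
  if (any(sdv == 0)) {
    warning("zero-variance feature(s) passed through centred: ",
            paste(colnames(tr)[sdv == 0], collapse = ", "))
    sdv[sdv == 0] <- 1
  }
  out <- sweep(sweep(ap, 2, mu), 2, sdv, "/")
  attr(out, "center") <- mu; attr(out, "scale") <- sdv
  out
}

# stratified k-fold assignment; errors when a class has fewer rows than k
# would leave some validation fold single-class by construction.
stratified_folds <- function(labels, k = 5, seed = NULL) {
  labels <- as.character(labels)
  fold <- integer(length(labels))
  with_seed(seed, {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      if (length(idx) < k)
        stop("class '", cl, "' has fewer samples than folds; re-stratify")
      fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  })
  fold
}

# one fold of the leakage-safe pipeline: z-score fit on fold-train, SMOTE
# the fold-train only, fit, score the untouched fold-validation rows.
run_fold <- function(spec, params, x, labels, train_idx, val_idx, seed) {
  xtr <- zscore_transform(x[train_idx, , drop = FALSE])
  xval <- zscore_transform(x[train_idx, , drop = FALSE],
                           x[val_idx, , drop = FALSE])
  bal <- smote_balance(xtr, labels[train_idx], seed = child_seed(seed, 1))
  model <- fit_classifier(spec, params, bal$features, bal$labels,
                          seed = child_seed(seed, 2))
  colnames(xval) <- colnames(x)
  probs <- predict_prob(model, xval)
  classification_metrics(probs, labels[val_idx], positive = model$positive)
}

#' Grid search with stratified cross-validation
#'
#' For every grid row: stratified `k`-fold CV with the per-fold pipeline
#' (z-score fit on fold-train, SMOTE on fold-train, fit, score the
#' fold-validation rows). The winner has the highest mean AUROC; ties are
#' broken by higher mean balanced accuracy, then grid order.
#'
#' @param spec a [model_spec()].
#' @param x feature matrix/data frame.
#' @param labels two-class labels.
#' @param k folds.
#' @param seed integer seed controlling folds, SMOTE and fits.
#' @return list with `best_params` (list), `best_index`, and `cv_table`
#'   (mean AUROC / balanced accuracy per grid row).
#' @export
grid_search_cv <- function(spec, x, labels, k = 5, seed = NULL) {
  stopifnot(inherits(spec, "model_spec"), nrow(spec$grid) >= 1)
  x <- as.matrix(x)
  fold <- stratified_folds(labels, k, seed = child_seed(seed, 99))
  res <- data.frame(auroc = numeric(nrow(spec$grid)),
                    balanced_accuracy = numeric(nrow(spec$grid)))
  for (g in seq_len(nrow(spec$grid))) {
    m <- vapply(seq_len(k), function(f) {
      run_fold(spec, spec$grid[g, , drop = FALSE], x, labels,
               which(fold != f), which(fold == f),
               seed = child_seed(seed, g * 10L + f))
    }, numeric(4))
    res$auroc[g] <- mean(m["auroc", ], na.rm = TRUE)
    res$balanced_accuracy[g] <- mean(m["balanced_accuracy", ], na.rm = TRUE)
  }
  ord <- order(-res$auroc, -res$balanced_accuracy, seq_len(nrow(res)))
  best <- ord[1]
  list(best_params = as.list(spec$grid[best, , drop = FALSE]),
       best_index = best, cv_table = cbind(spec$grid, res))
}

#' Cross-validated evaluation at fixed hyperparameters
#'
#' Stratified `k`-fold CV with the leakage-safe per-fold pipeline. Reports
#' per-fold accuracy, F1, balanced accuracy and AUROC; aggregates are means
#' and SDs, with a normal-approximation 95% CI for the mean AUROC
#' (`mean +/- 1.96 * sd / sqrt(k)`). Folds whose validation split is
#' single-class get an `NA` AUROC and are excluded from the AUROC mean with
#' a warning.
#'
#' @inheritParams grid_search_cv
#' @param params hyperparameters (one grid row or list).
#' @return list of class `model_evaluation` with `per_fold`, `mean`, `sd`,
#'   `auroc_ci`, `family`, `params`, `seed`.
#' @export
evaluate_cv <- function(spec, params, x, labels, k = 5, seed = NULL) {
  x <- as.matrix(x)
  fold <- stratified_folds(labels, k, seed = child_seed(seed, 99))
  per_fold <- t(vapply(seq_len(k), function(f) {
    run_fold(spec, params, x, labels, which(fold != f), which(fold == f),
             seed = child_seed(seed, 1000L + f))
  }, numeric(4)))
  per_fold <- as.data.frame(per_fold)
  if (anyNA(per_fold$auroc))
    warning(sum(is.na(per_fold$auroc)),
            " fold(s) had single-class validation data; excluded from AUROC")
  agg_mean <- colMeans(per_fold, na.rm = TRUE)
  agg_sd <- apply(per_fold, 2, stats::sd, na.rm = TRUE)
  k_eff <- sum(!is.na(per_fold$auroc))
  ci <- agg_mean[["auroc"]] +
    c(-1, 1) * 1.96 * agg_sd[["auroc"]] / sqrt(max(k_eff, 1))
  structure(list(per_fold = per_fold, mean = agg_mean, sd = agg_sd,
                 auroc_ci = ci, family = spec$family, params = params,
                 seed = seed),
            class = "model_evaluation")
}

#' @export
print.model_evaluation <- function(x, ...) {
  cat(sprintf("<model_evaluation> %s\n", x$family))
  cat(sprintf("  accuracy %.3f (SD %.3f)  F1 %.3f (SD %.3f)\n",
              x$mean[["accuracy"]], x$sd[["accuracy"]],
              x$mean[["f1"]], x$sd[["f1"]]))
  cat(sprintf("  balanced accuracy %.3f (SD %.3f)\n",
              x$mean[["balanced_accuracy"]], x$sd[["balanced_accuracy"]]))
  cat(sprintf("  mean AUROC %.3f (95%% CI %.3f-%.3f)\n",
              x$mean[["auroc"]], x$auroc_ci[1], x$auroc_ci[2]))
  invisible(x)
}

#' Final holdout evaluation
#'
#' Refits the pipeline on the full training set (z-score and SMOTE on the
#' training rows only) and scores the held-out test set once.
#'
#' @param spec a [model_spec()]; `params` its chosen hyperparameters.
#' @param params hyperparameters.
#' @param x_train,labels_train training data.
#' @param x_test,labels_test disjoint held-out data.
#' @param seed integer seed.
#' @return list with `metrics`, `probs` and the fitted `model`.
#' @export
evaluate_holdout <- function(spec, params, x_train, labels_train,
                             x_test, labels_test, seed = NULL) {
  if (!nrow(as.matrix(x_test))) stop("empty test set")
  xtr <- zscore_transform(x_train)
  xte <- zscore_transform(x_train, x_test)
  bal <- smote_balance(xtr, labels_train, seed = child_seed(seed, 1))
  model <- fit_classifier(spec, params, bal$features, bal$labels,
                          seed = child_seed(seed, 2))
  colnames(xte) <- colnames(as.matrix(x_train))
  probs <- predict_prob(model, xte)
  list(metrics = classification_metrics(probs, labels_test,
                                        positive = model$positive),
       probs = probs, model = model)
}

#' Train and evaluate the full protocol on a feature table
#'
#' Convenience wrapper: stratified 80/20 holdout, grid search CV on the
#' training split, cross-validated evaluation at the best hyperparameters,
#' one-time holdout evaluation, and (for tree ensembles) feature
#' importances.
#'
#' @param features data frame with feature columns and a label column.
#' @param label_col label column name.
#' @param feature_cols feature columns (default: selected automatically as
#'   in [compare_feature_table()]).
#' @param family model family.
#' @param grid optional hyperparameter grid.
#' @param seed master seed.
#' @param test_fraction holdout fraction.
#' @param k CV folds.
#' @return list with `cv` (a `model_evaluation`), `holdout`, `best_params`,
#'   `importance` (or `NULL`), `model`, `seed`.
#' @export
train_risk_model <- function(features, label_col = "label",
                             feature_cols = NULL,
                             family = "random_forest", grid = NULL,
                             seed = 1, test_fraction = 0.2, k = 5) {
  if (is.null(feature_cols)) {
    drop <- c("participant_id", "eye", "truth_group", "cvsq_pre",
              "cvsq_post", label_col)
    feature_cols <- setdiff(names(features)[vapply(features, is.numeric,
                                                   logical(1))], drop)
  }
  x <- as.matrix(features[, feature_cols, drop = FALSE])
  labels <- features[[label_col]]
  keep <- stats::complete.cases(x)
  x <- x[keep, , drop = FALSE]; labels <- labels[keep]
  spec <- model_spec(family, grid = grid, rng_seed = seed)
  split <- stratified_holdout_split(labels, test_fraction,
                                    seed = child_seed(seed, 7))
  xtr <- x[split$train, , drop = FALSE]; ytr <- labels[split$train]
  gs <- grid_search_cv(spec, xtr, ytr, k = k, seed = child_seed(seed, 11))
  cv <- evaluate_cv(spec, gs$best_params, xtr, ytr, k = k,
                    seed = child_seed(seed, 13))
  hold <- if (length(split$test)) {
    evaluate_holdout(spec, gs$best_params, xtr, ytr,
                     x[split$test, , drop = FALSE], labels[split$test],
                     seed = child_seed(seed, 17))
  } else NULL
  final_model <- if (!is.null(hold)) hold$model else {
    bal <- smote_balance(zscore_transform(xtr), ytr,
                         seed = child_seed(seed, 19))
    fit_classifier(spec, gs$best_params, bal$features, bal$labels,
                   seed = child_seed(seed, 23))
  }
  imp <- if (family %in% c("random_forest", "xgboost"))
    rank_feature_importance(final_model) else NULL
  # deployment models consume raw (unstandardised) features: remember stats
  final_model$center <- attr(zscore_transform(xtr), "center")
  final_model$scale <- attr(zscore_transform(xtr), "scale")
  list(cv = cv, holdout = if (!is.null(hold)) hold$metrics else NULL,
       best_params = gs$best_params, importance = imp,
       model = final_model, seed = seed, features = feature_cols)
}
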