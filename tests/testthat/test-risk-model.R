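test_that("stratified holdout preserves class proportions", {
  labels <- c(rep("deteriorated", 42), rep("nondeteriorated", 34))
  sp <- stratified_holdout_split(labels, 0.2, seed = 1)
  expect_length(sp$test, 15)  # round(42*.2) + round(34*.2) = 8 + 7
  expect_equal(sum(labels[sp$test] == "deteriorated"), 8)
  expect_equal(sum(labels[sp$test] == "nondeteriorated"), 7)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_identical(sp, stratified_holdout_split(labels, 0.2, seed = 1))
  all_train <- stratified_holdout_split(labels, 0)
  expect_length(all_train$test, 0)
  expect_error(stratified_holdout_split(c("a", "a", "b"), 0.5), "at least 2")
})

test_that("SMOTE balances 42 vs 34 to 42 per class", {
  set.seed(4)
  x <- matrix(rnorm(76 * 5), 76, 5)
  labels <- c(rep("majority", 42), rep("minority", 34))
  bal <- smote_balance(x, labels, seed = 2)
  expect_equal(as.integer(table(bal$labels)[c("majority", "minority")]),
               c(42L, 42L))
  # originals preserved unchanged, majority untouched
  expect_identical(bal$features[1:76, ], x)
  # already balanced: identity
  even <- smote_balance(x[1:20, ], rep(c("a", "b"), 10), seed = 2)
  expect_identical(even$features, x[1:20, ])
  expect_error(smote_balance(x, rep("a", 76)), "two classes")
})

test_that("every synthetic SMOTE point is a convex combination of minority
           neighbours", {
  set.seed(5)
  x <- matrix(rnorm(40 * 3), 40, 3)
  labels <- c(rep("maj", 25), rep("min", 15))
  bal <- smote_balance(x, labels, seed = 7)
  synth <- bal$features[-(1:40), , drop = FALSE]
  minority <- x[26:40, , drop = FALSE]
  for (i in seq_len(nrow(synth))) {
    s <- synth[i, ]
    on_segment <- FALSE
    for (a in seq_len(nrow(minority))) for (b in seq_len(nrow(minority))) {
      if (a == b) next
      d <- minority[b, ] - minority[a, ]
      if (sum(d^2) == 0) next
      u <- sum((s - minority[a, ]) * d) / sum(d^2)
      proj <- minority[a, ] + u * d
      if (u >= -1e-9 && u <= 1 + 1e-9 &&
          sqrt(sum((s - proj)^2)) < 1e-8) on_segment <- TRUE
    }
    expect_true(on_segment)
  }
})

test_that("z-scoring uses training statistics only", {
  set.seed(6)
  train <- matrix(rnorm(50 * 3, 10, 2), 50, 3)
  z <- zscore_transform(train)
  expect_equal(unname(colMeans(z)), rep(0, 3), tolerance = 1e-12)
  expect_equal(unname(apply(z, 2, sd)), rep(1, 3), tolerance = 1e-12)
  test <- matrix(rnorm(20 * 3, 20, 5), 20, 3)
  zt <- zscore_transform(train, test)
  own <- zscore_transform(test)
  expect_gt(max(abs(zt - own)), 0.5)   # train stats, not its own
  expect_equal(unname(zt[1, 1]),
               (test[1, 1] - mean(train[, 1])) / sd(train[, 1]))
  const <- cbind(train, 5)
  expect_warning(zc <- zscore_transform(const), "zero-variance")
  expect_equal(unname(zc[, 4]), rep(0, 50))
})

test_that("grid search picks the adequate configuration", {
  ft <- separable_features(20, seed = 2)
  spec <- model_spec("decision_tree",
                     grid = data.frame(max_depth = c(1, 5),
                                       min_leaf = c(30, 2)))
  # config 1 cannot split at all (min_leaf > n/2): constant classifier
  gs <- grid_search_cv(spec, ft[, 1:3], ft$label, seed = 3)
  expect_equal(gs$best_index, 2L)
  single <- model_spec("decision_tree", grid = data.frame(max_depth = 3,
                                                          min_leaf = 2))
  gs1 <- grid_search_cv(single, ft[, 1:3], ft$label, seed = 3)
  expect_equal(gs1$best_params$max_depth, 3)
  expect_identical(gs1$cv_table,
                   grid_search_cv(single, ft[, 1:3], ft$label,
                                  seed = 3)$cv_table)
})

test_that("cross-validated evaluation separates a separable cohort", {
  ft <- separable_features(25, seed = 4)
  ev <- evaluate_cv(fast_rf(), list(n_trees = 50, max_depth = Inf),
                    ft[, 1:3], ft$label, seed = 5)
  expect_equal(ev$mean[["auroc"]], 1.0)
  expect_equal(nrow(ev$per_fold), 5)
  expect_true(all(ev$per_fold$accuracy >= 0 & ev$per_fold$accuracy <= 1))
  # aggregation arithmetic equals hand-computed mean/sd of fold values
  expect_equal(ev$mean[["f1"]], mean(ev$per_fold$f1))
  expect_equal(ev$sd[["accuracy"]], sd(ev$per_fold$accuracy))
  expect_equal(ev$auroc_ci,
               ev$mean[["auroc"]] + c(-1, 1) * 1.96 * ev$sd[["auroc"]] /
                 sqrt(5))
})

test_that("holdout pipeline has no train/test information flow", {
  ft <- separable_features(25, seed = 6)
  x <- ft[, 1:3]; labels <- ft$label
  sp <- stratified_holdout_split(labels, 0.2, seed = 7)
  ho1 <- evaluate_holdout(fast_rf(), list(n_trees = 30), x[sp$train, ],
                          labels[sp$train], x[sp$test, ], labels[sp$test],
                          seed = 8)
  # identical rerun: byte-identical predictions
  ho2 <- evaluate_holdout(fast_rf(), list(n_trees = 30), x[sp$train, ],
                          labels[sp$train], x[sp$test, ], labels[sp$test],
                          seed = 8)
  expect_identical(ho1$probs, ho2$probs)
  # permuting test rows permutes predictions identically (no test fitting)
  perm <- sample(seq_along(sp$test))
  ho3 <- evaluate_holdout(fast_rf(), list(n_trees = 30), x[sp$train, ],
                          labels[sp$train], x[sp$test, ][perm, ],
                          labels[sp$test][perm], seed = 8)
  expect_identical(ho3$probs, ho1$probs[perm])
  expect_gt(ho1$metrics[["accuracy"]], 0.9)
  expect_error(evaluate_holdout(fast_rf(), list(n_trees = 30), x, labels,
                                x[0, ], labels[0]), "empty test")
})

test_that("degenerate validation labels yield sentinels", {
  probs <- c(0.9, 0.8, 0.2)
  m <- classification_metrics(probs, rep("deteriorated", 3))
  expect_true(is.na(m[["balanced_accuracy"]]))
  expect_true(is.na(m[["auroc"]]))
  # constant classifier: balanced accuracy 0.5
  m2 <- classification_metrics(rep(1, 10),
                               rep(c("deteriorated", "nondeteriorated"), 5))
  expect_equal(m2[["balanced_accuracy"]], 0.5)
})

test_that("feature importance is normalised and finds planted signal", {
  ft <- separable_features(25, seed = 9)
  names(ft)[1] <- "avg_blink_duration"
  bal <- smote_balance(ft[, 1:3], ft$label, seed = 1)
  model <- fit_classifier(fast_rf(), list(n_trees = 50), bal$features,
                          bal$labels, seed = 2)
  imp <- rank_feature_importance(model)
  expect_equal(imp$feature[1], "avg_blink_duration")
  expect_equal(sum(imp$importance), 1, tolerance = 1e-9)
  expect_true(all(imp$importance >= 0))
  tree <- fit_classifier(fast_tree(), list(max_depth = 3), bal$features,
                         bal$labels)
  expect_error(rank_feature_importance(tree), "ensemble")
})

test_that("all four families train, predict probabilities, and refuse bad schemas", {
  ft <- separable_features(15, seed = 10)
  bal <- smote_balance(zscore_transform(ft[, 1:3]), ft$label, seed = 1)
  params <- list(decision_tree = list(max_depth = 3, min_leaf = 2),
                 random_forest = list(n_trees = 30),
                 xgboost = list(n_rounds = 30, depth = 3,
                                learning_rate = 0.1),
                 svm_rbf_pca = list(cost = 1, gamma = 0.5))
  for (fam in names(params)) {
    model <- fit_classifier(model_spec(fam), params[[fam]], bal$features,
                            bal$labels, seed = 3)
    p <- predict_prob(model, bal$features)
    expect_true(all(p >= 0 & p <= 1))
    expect_gt(auroc(p, bal$labels == "deteriorated"), 0.95)
    expect_error(predict_prob(model, data.frame(bogus = 1)),
                 "schema mismatch")
  }
})

test_that("train_risk_model wires the whole protocol together", {
  ft <- separable_features(20, seed = 11)
  res <- train_risk_model(ft, feature_cols = c("sig", "noise1", "noise2"),
                          family = "random_forest",
                          grid = data.frame(n_trees = 40, max_depth = Inf),
                          seed = 12)
  expect_s3_class(res$cv, "model_evaluation")
  expect_gt(res$cv$mean[["auroc"]], 0.95)
  expect_named(res$holdout,
               c("accuracy", "f1", "balanced_accuracy", "auroc"))
  expect_equal(res$importance$feature[1], "sig")
  # reproducible end to end
  res2 <- train_risk_model(ft, feature_cols = c("sig", "noise1", "noise2"),
                           family = "random_forest",
                           grid = data.frame(n_trees = 40, max_depth = Inf),
                           seed = 12)
  expect_identical(res$cv$per_fold, res2$cv$per_fold)
  expect_identical(res$holdout, res2$holdout)
})
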