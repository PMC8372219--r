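# Repeated-CV tuning: structural contracts, determinism, and signal
# recovery on planted data.

train_fixture <- function(seed = 1, n = 120, p = 6, effect = 2) {
  planted_binary(seed, n = n, p = p, n_informative = 3, effect = effect)$dataset
}

test_that("cv_table has one row per combination and kfold x cv_times resamples", {
  d <- train_fixture()
  tr <- tune_and_train(d, "glmnet_logistic", kfold = 5, cv_times = 2, seed = 1)
  expect_equal(nrow(tr$cv_table), 6)         # 1 alpha x 6 lambda
  expect_true(all(tr$cv_table$n_resamples == 10))
  vals <- attr(tr$cv_table, "resample_values")
  expect_equal(dim(vals), c(6, 10))
  # the mean of each combination lies within its resample range
  expect_true(all(tr$cv_table$mean_metric >= apply(vals, 1, min) - 1e-12))
  expect_true(all(tr$cv_table$mean_metric <= apply(vals, 1, max) + 1e-12))
})

test_that("a single-combination grid is returned as best unchanged", {
  d <- train_fixture()
  g <- structure(list(model_type = "glmnet_logistic",
                      params = list(alpha = 0, lambda = 0.1)), class = "ml_grid")
  tr <- tune_and_train(d, "glmnet_logistic", grid = g, kfold = 3, cv_times = 1,
                       seed = 2)
  expect_equal(nrow(tr$cv_table), 1)
  expect_equal(tr$best_params, list(alpha = 0, lambda = 0.1))
})

test_that("tuning is deterministic under a fixed seed", {
  d <- train_fixture()
  tr1 <- tune_and_train(d, "glmnet_logistic", kfold = 3, cv_times = 2, seed = 7)
  tr2 <- tune_and_train(d, "glmnet_logistic", kfold = 3, cv_times = 2, seed = 7)
  expect_equal(tr1$cv_table, tr2$cv_table)
  expect_equal(tr1$best_params, tr2$best_params)
})

test_that("CV folds partition the training set stratified by class", {
  y <- rep(c("a", "b"), c(30, 20))
  folds <- tabml:::stratified_kfold(y, 5, seed = 3)
  expect_equal(sort(unique(folds)), 1:5)
  expect_true(all(table(folds) == 10))
  expect_true(all(table(folds, y)[, "a"] == 6))
  expect_true(all(table(folds, y)[, "b"] == 4))
})

test_that("planted logistic signal is recovered with high CV AUROC", {
  hits <- 0
  for (seed in 1:3) {
    d <- planted_binary(seed, n = 200, p = 10, n_informative = 5, effect = 2)$dataset
    tr <- tune_and_train(d, "glmnet_logistic", kfold = 5, cv_times = 3,
                         seed = seed)
    if (max(tr$cv_table$mean_metric) >= 0.9) hits <- hits + 1
  }
  expect_gte(hits, 2)
})

test_that("precondition violations error clearly", {
  d <- train_fixture()
  expect_error(tune_and_train(d, "glmnet_logistic", kfold = 200, cv_times = 1,
                              seed = 1), "smallest class")
  expect_error(tune_and_train(d, "glmnet_logistic", metric = "rmse",
                              kfold = 3, cv_times = 1, seed = 1), "undefined")
  expect_error(tune_and_train(d, "glmnet_linear", kfold = 3, cv_times = 1,
                              seed = 1), "continuous outcome")
})

test_that("every model type fits, scores and predicts on both outcome kinds", {
  db <- planted_binary(4, n = 60, p = 4, n_informative = 2, effect = 2)$dataset
  x <- tabml:::dataset_matrix(db)
  y <- db$table$outcome
  dr <- generate_dataset(synth_spec(n_samples = 60, n_continuous = 4,
                                    n_informative = 2, effect_sizes = 1,
                                    outcome_kind = "continuous", seed = 4))$dataset
  xr <- tabml:::dataset_matrix(dr)
  yr <- dr$table$outcome
  cases <- list(
    list("glmnet_logistic", list(alpha = 0, lambda = 0.1), "binary"),
    list("svm_rbf", list(cost = 1, gamma = 0.25), "binary"),
    list("decision_tree", list(maxdepth = 4), "binary"),
    list("random_forest", list(mtry = 2), "binary"),
    list("xgboost", list(eta = 0.3, max_depth = 2, nrounds = 20), "binary"),
    list("glmnet_linear", list(alpha = 0, lambda = 0.1), "continuous"),
    list("svm_rbf", list(cost = 1, gamma = 0.25), "continuous"),
    list("decision_tree", list(maxdepth = 4), "continuous"),
    list("random_forest", list(mtry = 2), "continuous"),
    list("xgboost", list(eta = 0.3, max_depth = 2, nrounds = 20), "continuous")
  )
  for (cs in cases) {
    kind <- cs[[3]]
    xx <- if (kind == "binary") x else xr
    yy <- if (kind == "binary") y else yr
    m <- tabml:::fit_model(xx, yy, cs[[1]], cs[[2]], kind, seed = 1)
    sc <- score_model(m, xx)
    if (kind == "binary") {
      expect_equal(dim(sc), c(nrow(xx), 2))
      expect_true(all(sc >= 0 & sc <= 1))
      expect_equal(unname(rowSums(sc)), rep(1, nrow(xx)), tolerance = 1e-6)
      expect_true(all(predict(m, xx) %in% c("neg", "pos")))
    } else {
      expect_length(sc, nrow(xx))
      expect_true(is.numeric(predict(m, xx)))
    }
    # refitting with the same seed reproduces the scores
    m2 <- tabml:::fit_model(xx, yy, cs[[1]], cs[[2]], kind, seed = 1)
    expect_equal(score_model(m2, xx), sc, tolerance = 1e-10)
  }
})
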