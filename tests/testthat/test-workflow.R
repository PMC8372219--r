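# End-to-end run_ml / run_many orchestration and cross-run summaries.

stub_run <- function(seed, metrics, cv_table = NULL, cv_metric = 0.8,
                     model = "glmnet_logistic") {
  structure(list(
    model_type = model, seed = seed,
    performance = list(metrics = metrics),
    cv_metric = cv_metric,
    train_result = list(metric_name = "auroc", maximize = TRUE,
                        cv_table = cv_table)
  ), class = "ml_run")
}

run_comparable <- function(r) {
  list(r$best_params, r$cv_table, r$split$train_indices,
       r$performance$metrics, if (is.null(r$importance)) NULL
       else as.data.frame(r$importance))
}

test_that("run_ml is deterministic and honours find_importance", {
  d <- planted_binary(1, n = 100, p = 5, n_informative = 2, effect = 2)$dataset
  r1 <- run_ml(d, "glmnet_logistic", cv_times = 2, seed = 4)
  r2 <- run_ml(d, "glmnet_logistic", cv_times = 2, seed = 4)
  expect_equal(run_comparable(r1), run_comparable(r2))
  expect_null(r1$importance)
  r3 <- run_ml(d, "glmnet_logistic", cv_times = 2, seed = 4,
               find_importance = TRUE, nperm = 5)
  expect_s3_class(r3$importance, "ml_importance")
  expect_equal(run_comparable(r3)[1:4], run_comparable(r1)[1:4])
})

test_that("run_ml recovers a planted signal on held-out data", {
  sim <- generate_dataset(synth_spec(n_samples = 200, n_continuous = 20,
                                     n_informative = 5, effect_sizes = 2,
                                     seed = 11))
  r <- run_ml(sim$dataset, "glmnet_logistic", cv_times = 2, seed = 11)
  expect_gt(r$performance$metrics[["auroc"]], 0.8)
})

test_that("run_ml derives every stage seed from the top-level seed", {
  d <- planted_binary(2, n = 100, p = 5, n_informative = 2, effect = 2)$dataset
  r1 <- run_ml(d, "glmnet_logistic", cv_times = 1, seed = 1)
  r2 <- run_ml(d, "glmnet_logistic", cv_times = 1, seed = 2)
  expect_false(identical(r1$split$train_indices, r2$split$train_indices))
  expect_equal(r1$split$seed, derive_seed(1, "split"))
})

test_that("run_ml auto-preprocesses raw tables and refuses when told not to", {
  tab <- data.frame(dx = rep(c("h", "d"), 30), site = sample(c("a", "b"), 60, TRUE),
                    x = rnorm(60), stringsAsFactors = FALSE)
  d <- ml_dataset(tab, "dx")
  r <- run_ml(d, "glmnet_logistic", cv_times = 1, seed = 1)
  expect_s3_class(r$preprocess, "ml_preprocess")
  expect_error(run_ml(d, "glmnet_logistic", cv_times = 1, seed = 1,
                      preprocess = FALSE), "preprocess")
})

test_that("grouped runs keep every group on one side of the split", {
  sim <- generate_dataset(synth_spec(n_samples = 120, n_continuous = 5,
                                     n_informative = 2, effect_sizes = 1,
                                     n_groups = 6, seed = 3))
  r <- run_ml(sim$dataset, "glmnet_logistic", cv_times = 1, seed = 5,
              group_split = TRUE)
  g <- sim$dataset$group_labels
  expect_length(intersect(unique(g[r$split$train_indices]),
                          unique(g[r$split$test_indices])), 0)
})

test_that("run_many yields one independent record per seed", {
  d <- planted_binary(6, n = 80, p = 4, n_informative = 2, effect = 1)$dataset
  runs <- run_many(d, "glmnet_logistic", seeds = 1:5, cv_times = 1)
  expect_length(runs, 5)
  splits <- lapply(runs, function(r) r$split$train_indices)
  expect_gt(length(unique(splits)), 1)  # different seeds, different splits
  expect_error(run_many(d, "glmnet_logistic", seeds = c(1, 1), cv_times = 1),
               "duplicate")
  # disjoint seed sets concatenated equal the union
  ra <- run_many(d, "glmnet_logistic", seeds = 1:2, cv_times = 1)
  rb <- run_many(d, "glmnet_logistic", seeds = 3, cv_times = 1)
  expect_equal(lapply(c(ra, rb), run_comparable),
               lapply(runs[1:3], run_comparable))
})

test_that("serial and parallel run_many produce identical results", {
  d <- planted_binary(7, n = 80, p = 4, n_informative = 2, effect = 1)$dataset
  serial <- run_many(d, "glmnet_logistic", seeds = 1:4, cv_times = 1)
  parallel <- run_many(d, "glmnet_logistic", seeds = 1:4, cv_times = 1,
                       n_cores = 2)
  expect_equal(lapply(serial, run_comparable), lapply(parallel, run_comparable))
})

test_that("summarize_performance computes the documented statistics", {
  one <- stub_run(1, c(auroc = 0.7))
  s1 <- summarize_performance(list(one))
  expect_equal(s1$sd[s1$metric == "auroc"], 0)
  expect_equal(s1$mean[s1$metric == "auroc"], 0.7)

  two <- list(stub_run(1, c(auroc = 0.7)), stub_run(2, c(auroc = 0.9)))
  s2 <- summarize_performance(two)
  row <- s2[s2$metric == "auroc", ]
  expect_equal(row$mean, 0.8)
  expect_equal(row$sd, sd(c(0.7, 0.9)))
  expect_equal(row$n, 2)

  mixed <- c(two, list(stub_run(3, c(auroc = 0.6), model = "random_forest")))
  s3 <- summarize_performance(mixed)
  expect_equal(sort(unique(s3$model_type)), c("glmnet_logistic", "random_forest"))
  expect_equal(nrow(s3[s3$metric == "auroc", ]), 2)
})

test_that("summarising a single real run reproduces its metrics exactly", {
  d <- planted_binary(8, n = 80, p = 4, n_informative = 2, effect = 1)$dataset
  r <- run_ml(d, "glmnet_logistic", cv_times = 1, seed = 1)
  s <- summarize_performance(list(r))
  for (m in names(r$performance$metrics)) {
    expect_equal(s$mean[s$metric == m], unname(r$performance$metrics[[m]]))
  }
})

test_that("hp_performance_table flags grid-edge winners", {
  cv <- function(lams, means) {
    data.frame(alpha = 0, lambda = lams, mean_metric = means,
               sd_metric = 0.01, n_resamples = 10)
  }
  edge <- stub_run(1, c(auroc = 0.8), cv_table = cv(c(0.1, 1, 10), c(0.9, 0.8, 0.7)))
  tab <- hp_performance_table(list(edge), "lambda")
  expect_true(all(tab$boundary_warning))
  mid <- stub_run(1, c(auroc = 0.8), cv_table = cv(c(0.1, 1, 10), c(0.7, 0.9, 0.8)))
  tab2 <- hp_performance_table(list(mid), "lambda")
  expect_false(any(tab2$boundary_warning))
  expect_equal(nrow(tab2), 3)
  # aggregation across records averages the per-combination means
  both <- list(edge, mid)
  tab3 <- hp_performance_table(both, "lambda")
  expect_equal(tab3$mean_metric[tab3$value == 0.1], mean(c(0.9, 0.7)))
  expect_equal(tab3$n, rep(2, 3))
  expect_error(hp_performance_table(both, "gamma"), "lambda")
})
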