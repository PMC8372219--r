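# End-to-end pipeline: split -> tune/train -> evaluate -> (optional)
# permutation importance, all driven by one top-level seed; and the
# many-seeds workflow that quantifies split-to-split performance variation.

#' Run the full supervised ML pipeline once
#'
#' Splits the data into train and test sets (outcome-stratified by default,
#' or group-aware with `group_split = TRUE`), tunes hyperparameters by
#' repeated k-fold cross-validation on the training set, refits the best
#' combination, evaluates it on the held-out test set, and optionally
#' computes permutation-test feature importance. Every stage draws its seed
#' deterministically from `seed` via [derive_seed()], so a run is fully
#' reproducible from `(dataset, arguments)`.
#'
#' Non-numeric features are preprocessed automatically with
#' [preprocess_data()] defaults (set `preprocess = TRUE` to force, `FALSE`
#' to forbid); the preprocessing statistics are fitted on the full dataset
#' before splitting, which mirrors the reference workflow but leaks the
#' scaling means/sds across the split — see the methods vignette.
#'
#' @param dataset An [ml_dataset].
#' @param model_type One of the supported model types; see [default_grid()].
#' @param training_frac Fraction of samples used for training (default 0.8).
#' @param kfold Number of CV folds (default 5).
#' @param cv_times Number of CV repetitions (default 100; use fewer for
#'   desk-scale runs).
#' @param metric Tuning/reporting metric; defaults by outcome kind.
#' @param seed Top-level integer seed.
#' @param find_importance Compute permutation importance (default `FALSE`).
#' @param nperm Permutations per feature group (default 100).
#' @param group_split Split by `dataset$group_labels` instead of stratifying
#'   on the outcome (default `FALSE`).
#' @param grid Optional `ml_grid` overriding the default hyperparameter grid.
#' @param preprocess `"auto"` (default: preprocess when any feature is
#'   non-numeric), `TRUE` or `FALSE`.
#' @param groups Named list mapping kept features to the members permuted
#'   together for importance, as in [preprocess_data()]`$correlated_groups`.
#'   Supply this when the data were preprocessed outside `run_ml()`;
#'   ignored when preprocessing runs internally (the internal bookkeeping
#'   is used), and `NULL` otherwise treats every feature as its own group.
#' @param positive Positive-class label for binary outcomes; defaults to the
#'   lexicographically second outcome level.
#' @return An object of class `ml_run`: list with `model_type`, `seed`,
#'   `split` (`ml_split`), `split_sizes`, `train_result` (`ml_train`),
#'   `best_params`, `cv_metric` (best combination's mean CV metric),
#'   `performance` (`ml_performance`), `importance` (`ml_importance` or
#'   `NULL`), `preprocess` (`ml_preprocess` or `NULL`) and `config`.
#' @examples
#' sim <- generate_dataset(synth_spec(n_samples = 100, n_continuous = 5,
#'                                    n_informative = 3, effect_sizes = 2))
#' fit <- run_ml(sim$dataset, "glmnet_logistic", cv_times = 2, seed = 1)
#' fit$performance$metrics[["auroc"]]
#' @export
run_ml <- function(dataset, model_type, training_frac = 0.8, kfold = 5,
                   cv_times = 100, metric = NULL, seed = 1,
                   find_importance = FALSE, nperm = 100, group_split = FALSE,
                   grid = NULL, preprocess = "auto", positive = NULL,
                   groups = NULL) {
  stopifnot(inherits(dataset, "ml_dataset"))
  if (!model_type %in% SUPPORTED_MODELS) stop_unknown_model(model_type)
  stopifnot(training_frac > 0, training_frac < 1, kfold >= 2, cv_times >= 1,
            nperm >= 1)
  config <- list(model_type = model_type, training_frac = training_frac,
                 kfold = kfold, cv_times = cv_times, metric = metric,
                 seed = seed, find_importance = find_importance, nperm = nperm,
                 group_split = group_split, preprocess = preprocess)

  has_nonnum <- any(!vapply(dataset_features(dataset), is.numeric, TRUE))
  do_pp <- if (identical(preprocess, "auto")) has_nonnum else isTRUE(preprocess)
  if (has_nonnum && !do_pp) {
    stop("dataset has non-numeric features; preprocess it first or set preprocess = TRUE",
         call. = FALSE)
  }
  pp <- NULL
  if (do_pp) {
    pp <- tryCatch(preprocess_data(dataset),
                   error = function(e) stop(sprintf("preprocess: %s",
                                                    conditionMessage(e)), call. = FALSE))
    dataset <- pp$dataset
    groups <- pp$correlated_groups
  }

  split <- tryCatch({
    if (isTRUE(group_split)) {
      if (is.null(dataset$group_labels)) {
        stop("group_split = TRUE but the dataset has no group labels")
      }
      grouped_split(dataset$group_labels, training_frac, derive_seed(seed, "split"))
    } else {
      stratified_split(dataset_outcome(dataset), training_frac,
                       derive_seed(seed, "split"))
    }
  }, error = function(e) stop(sprintf("split: %s", conditionMessage(e)), call. = FALSE))

  train <- subset_dataset(dataset, split$train_indices)
  test <- subset_dataset(dataset, split$test_indices)

  tr <- tryCatch(
    tune_and_train(train, model_type, grid = grid, kfold = kfold,
                   cv_times = cv_times, metric = metric,
                   seed = derive_seed(seed, "train"), positive = positive),
    error = function(e) stop(sprintf("train: %s", conditionMessage(e)), call. = FALSE))

  perf <- tryCatch(calc_performance(tr$model, test, positive = positive),
                   error = function(e) stop(sprintf("evaluate: %s",
                                                    conditionMessage(e)), call. = FALSE))

  imp <- NULL
  if (isTRUE(find_importance)) {
    imp <- tryCatch(
      permutation_importance(tr$model, test, groups = groups,
                             metric = tr$metric_name, nperm = nperm,
                             seed = derive_seed(seed, "importance"),
                             positive = positive),
      error = function(e) stop(sprintf("importance: %s", conditionMessage(e)),
                               call. = FALSE))
  }

  structure(
    list(model_type = model_type, seed = seed, split = split,
         split_sizes = c(train = length(split$train_indices),
                         test = length(split$test_indices)),
         train_result = tr, best_params = tr$best_params,
         cv_metric = tr$cv_table$mean_metric[best_row(tr)],
         performance = perf, importance = imp, preprocess = pp,
         config = config),
    class = "ml_run"
  )
}

#' @export
print.ml_run <- function(x, ...) {
  cat(sprintf("<ml_run> %s, seed %d: %d train / %d test\n",
              x$model_type, x$seed, x$split_sizes[["train"]],
              x$split_sizes[["test"]]))
  cat(sprintf("  best params: %s\n",
              paste(names(x$best_params), unlist(x$best_params),
                    sep = "=", collapse = ", ")))
  cat(sprintf("  CV %s = %.4f\n", x$train_result$metric_name, x$cv_metric))
  m <- x$performance$metrics
  cat("  test:", paste(names(m), signif(m, 4), sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.ml_run <- function(object, ...) {
  print(object)
  if (!is.null(object$importance)) {
    cat("top importance groups:\n")
    print.data.frame(utils::head(as.data.frame(object$importance), 5))
  }
  invisible(object)
}

#' @export
predict.ml_run <- function(object, newdata, ...) {
  predict(object$train_result$model, newdata, ...)
}

#' @export
plot.ml_run <- function(x, ...) {
  rp <- x$performance$roc_points
  if (is.null(rp)) {
    stop("no ROC curve available (non-binary outcome)", call. = FALSE)
  }
  graphics::plot(rp$fpr, rp$tpr, type = "l",
                 xlab = "False positive rate", ylab = "True positive rate",
                 main = sprintf("%s (AUROC = %.3f)", x$model_type,
                                x$performance$metrics[["auroc"]]), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' Run the pipeline across many train/test splits
#'
#' Calls [run_ml()] once per seed. Because test performance depends on the
#' particular train/test split drawn, a single split can be misleading; the
#' spread across many seeds is the honest summary. Records are independent
#' (each seed carries all its randomness), so parallel execution gives
#' results identical to serial.
#'
#' @param dataset An [ml_dataset].
#' @param model_type Model type passed to [run_ml()].
#' @param seeds Vector of unique integer seeds, one run per seed.
#' @param ... Further arguments to [run_ml()].
#' @param n_cores Number of worker processes (1 = serial; forked workers via
#'   the parallel package otherwise).
#' @return An object of class `ml_run_list` (a list of `ml_run`).
#' @export
run_many <- function(dataset, model_type, seeds, ..., n_cores = 1) {
  if (length(seeds) == 0) stop("seeds must be non-empty", call. = FALSE)
  if (anyDuplicated(seeds)) stop("duplicate seeds are not allowed", call. = FALSE)
  f <- function(s) run_ml(dataset, model_type, seed = s, ...)
  runs <- if (n_cores > 1) {
    parallel::mclapply(seeds, f, mc.cores = n_cores)
  } else {
    lapply(seeds, f)
  }
  structure(runs, class = "ml_run_list")
}

#' @export
print.ml_run_list <- function(x, ...) {
  cat(sprintf("<ml_run_list> %d runs\n", length(x)))
  print(summarize_performance(x))
  invisible(x)
}

#' @export
summary.ml_run_list <- function(object, ...) summarize_performance(object)

#' Summarise performance across runs
#'
#' Long-format summary suitable for box plots: per model type and metric,
#' the mean, sd, median, min and max of the held-out test metrics and of the
#' best cross-validation metric (reported as `cv_<metric>`). The sd of a
#' single record is reported as 0.
#'
#' @param records An `ml_run_list` or list of `ml_run` objects.
#' @return A data.frame with columns `model_type`, `metric`, `mean`, `sd`,
#'   `median`, `min`, `max`, `n`.
#' @export
summarize_performance <- function(records) {
  records <- as_run_list(records)
  rows <- list()
  for (r in records) {
    vals <- c(r$performance$metrics,
              stats::setNames(r$cv_metric, paste0("cv_", r$train_result$metric_name)))
    rows[[length(rows) + 1L]] <- data.frame(
      model_type = r$model_type, seed = r$seed,
      metric = names(vals), value = as.numeric(vals),
      stringsAsFactors = FALSE)
  }
  long <- do.call(rbind, rows)
  long <- long[!is.na(long$value), , drop = FALSE]
  out <- do.call(rbind, lapply(split(long, list(long$model_type, long$metric),
                                     drop = TRUE), function(d) {
    data.frame(model_type = d$model_type[1], metric = d$metric[1],
               mean = mean(d$value),
               sd = if (nrow(d) > 1) stats::sd(d$value) else 0,
               median = stats::median(d$value),
               min = min(d$value), max = max(d$value), n = nrow(d),
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$model_type, out$metric), , drop = FALSE]
  rownames(out) <- NULL
  out
}

as_run_list <- function(records) {
  if (inherits(records, "ml_run")) return(list(records))
  stopifnot(length(records) >= 1, all(vapply(records, inherits, TRUE, "ml_run")))
  records
}

#' Cross-validation performance by hyperparameter value
#'
#' Aggregates the tuning results of one or more runs (all sharing a model
#' type) by the values of one hyperparameter: per value, the
#' resample-weighted mean and the sd of the per-combination CV means. The
#' `boundary_warning` flag is set when the best mean sits on the edge of the
#' searched range — the signal that the grid is not being searched
#' exhaustively and should be widened.
#'
#' @param records An `ml_run_list` or list of `ml_run` objects with a common
#'   `model_type`.
#' @param param_name Name of a tuned hyperparameter.
#' @return A data.frame with columns `value`, `mean_metric`, `sd_metric`,
#'   `n`, `boundary_warning` (plus a matching `boundary_warning` attribute).
#' @export
hp_performance_table <- function(records, param_name) {
  records <- as_run_list(records)
  types <- unique(vapply(records, `[[`, "", "model_type"))
  if (length(types) != 1) stop("all records must share one model_type", call. = FALSE)
  cv <- records[[1]]$train_result$cv_table
  param_cols <- setdiff(names(cv), c("mean_metric", "sd_metric", "n_resamples"))
  if (!param_name %in% param_cols) {
    stop(sprintf("unknown parameter '%s'; grid parameters: %s", param_name,
                 paste(param_cols, collapse = ", ")), call. = FALSE)
  }
  all_cv <- do.call(rbind, lapply(records, function(r) r$train_result$cv_table))
  vals <- sort(unique(all_cv[[param_name]]))
  agg <- do.call(rbind, lapply(vals, function(v) {
    d <- all_cv[all_cv[[param_name]] == v, , drop = FALSE]
    data.frame(value = v,
               mean_metric = sum(d$mean_metric * d$n_resamples) / sum(d$n_resamples),
               sd_metric = if (nrow(d) > 1) stats::sd(d$mean_metric) else 0,
               n = nrow(d), stringsAsFactors = FALSE)
  }))
  maximize <- records[[1]]$train_result$maximize
  best <- if (maximize) which.max(agg$mean_metric) else which.min(agg$mean_metric)
  boundary <- best %in% c(1L, nrow(agg)) && nrow(agg) > 1L
  agg$boundary_warning <- boundary
  attr(agg, "boundary_warning") <- boundary
  agg
}
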