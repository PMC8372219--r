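# Hyperparameter tuning by repeated, outcome-stratified k-fold
# cross-validation on the training set, followed by a refit of the best
# combination on the full training set.

# Fold assignment stratified per class: within each class, shuffled indices
# are dealt round-robin across folds, so fold sizes per class differ by at
# most one.  Continuous outcomes are stratified on quartile bins.
stratified_kfold <- function(outcome, kfold, seed) {
  labels <- stratum_labels(outcome)
  n <- length(labels)
  folds <- integer(n)
  with_seed(seed, {
    offset <- 0L
    for (cl in sort(unique(labels))) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      folds[idx] <- ((seq_along(idx) - 1L + offset) %% kfold) + 1L
      offset <- offset + length(idx)
    }
  })
  folds
}

folds_valid <- function(folds, outcome, kfold, classif) {
  if (length(unique(folds)) != kfold) return(FALSE)
  if (!classif) return(TRUE)
  # every fold (and hence every fold complement) must contain every class
  all(vapply(seq_len(kfold), function(f) {
    length(unique(outcome[folds == f])) == length(unique(outcome))
  }, TRUE))
}

#' Tune hyperparameters by repeated cross-validation and fit the best model
#'
#' For each of `cv_times` repetitions, draws an outcome-stratified k-fold
#' partition of the training set under a repetition-specific sub-seed and
#' evaluates every hyperparameter combination on every held-out fold with
#' the chosen metric. The cross-validation table aggregates all
#' `kfold * cv_times` resamples per combination; the best combination
#' (ties break toward the earlier combination in enumeration order) is then
#' refitted on the whole training set.
#'
#' @param train An [ml_dataset] with all-numeric features (the training
#'   portion of a split).
#' @param model_type One of the supported model types; see [default_grid()].
#' @param grid An `ml_grid`, or `NULL` for the model's default grid.
#' @param kfold Number of folds (must not exceed the smallest training-class
#'   count for classification).
#' @param cv_times Number of independent k-fold repetitions.
#' @param metric Tuning metric (`"auroc"` for classification and `"rmse"`
#'   for regression by default).
#' @param seed Integer seed controlling fold draws and stochastic learners.
#' @param positive Positive-class label for binary outcomes.
#' @return An object of class `ml_train`: list with `best_params`,
#'   `cv_table` (one row per combination: parameter columns, `mean_metric`,
#'   `sd_metric`, `n_resamples`), `model` (the refitted `ml_model`),
#'   `metric_name`, `maximize` and `seed`.
#' @export
tune_and_train <- function(train, model_type, grid = NULL, kfold = 5,
                           cv_times = 10, metric = NULL, seed = 1,
                           positive = NULL) {
  x <- dataset_matrix(train)
  y <- dataset_outcome(train)
  kind <- train$outcome_kind
  check_model_outcome(model_type, kind)
  classif <- is_classification(kind)
  if (is.null(metric)) metric <- default_metric(kind)
  check_metric(metric, kind)
  if (classif) {
    counts <- table(as.character(y))
    if (kfold > min(counts)) {
      stop(sprintf("kfold = %d exceeds the smallest class count (%d)",
                   kfold, min(counts)), call. = FALSE)
    }
    if (is.null(positive) && kind == "binary") positive <- sort(names(counts))[2]
  }
  if (is.null(grid)) grid <- default_grid(model_type, ncol(x), x = x)
  stopifnot(inherits(grid, "ml_grid"), grid$model_type == model_type)
  combos <- grid_combinations(grid)
  n_combo <- nrow(combos)

  values <- matrix(NA_real_, nrow = n_combo, ncol = kfold * cv_times)
  for (rep in seq_len(cv_times)) {
    folds <- NULL
    for (attempt in 0:10) {
      cand <- stratified_kfold(y, kfold, derive_seed(seed, "cv", rep, attempt))
      if (folds_valid(cand, y, kfold, classif)) { folds <- cand; break }
    }
    if (is.null(folds)) {
      warning(sprintf("repetition %d: no class-complete fold draw found in 10 attempts; using the last draw", rep),
              call. = FALSE)
      folds <- cand
    }
    for (f in seq_len(kfold)) {
      hold <- folds == f
      for (ci in seq_len(n_combo)) {
        params <- as.list(combos[ci, , drop = FALSE])
        fit <- fit_model(x[!hold, , drop = FALSE], y[!hold], model_type,
                         params, kind,
                         seed = derive_seed(seed, "fit", rep, f, ci),
                         positive = positive)
        sc <- score_model(fit, x[hold, , drop = FALSE])
        values[ci, (rep - 1L) * kfold + f] <-
          eval_metric(metric, sc, y[hold], kind, positive = positive)
      }
    }
  }

  cv_table <- cbind(
    combos,
    data.frame(mean_metric = rowMeans(values),
               sd_metric = apply(values, 1, stats::sd),
               n_resamples = rowSums(!is.na(values)))
  )
  attr(cv_table, "resample_values") <- values
  maximize <- metric_maximize(metric)
  best_idx <- if (maximize) which.max(cv_table$mean_metric) else which.min(cv_table$mean_metric)
  best_params <- as.list(combos[best_idx, , drop = FALSE])
  model <- fit_model(x, y, model_type, best_params, kind,
                     seed = derive_seed(seed, "final_fit"), positive = positive)

  structure(
    list(best_params = best_params, cv_table = cv_table, model = model,
         metric_name = metric, maximize = maximize, seed = seed,
         model_type = model_type, kfold = kfold, cv_times = cv_times),
    class = "ml_train"
  )
}

#' @export
print.ml_train <- function(x, ...) {
  cat(sprintf("<ml_train> %s tuned over %d combination(s), %dx%d-fold CV (%s)\n",
              x$model_type, nrow(x$cv_table), x$cv_times, x$kfold, x$metric_name))
  cat("  best:", paste(names(x$best_params), unlist(x$best_params),
                       sep = "=", collapse = ", "),
      sprintf(" (mean %s = %.4f)\n", x$metric_name,
              x$cv_table$mean_metric[best_row(x)]))
  invisible(x)
}

best_row <- function(train_result) {
  if (train_result$maximize) which.max(train_result$cv_table$mean_metric)
  else which.min(train_result$cv_table$mean_metric)
}
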