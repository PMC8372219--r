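# Permutation-test feature importance on the held-out test set.  Perfectly
# correlated features (as grouped by preprocessing) are permuted together
# with one shared row permutation, so intra-group correlation is preserved
# while the group's link to the outcome is broken.

#' Permutation-test feature importance
#'
#' For each feature group, repeats `nperm` times: jointly permutes the rows
#' of all member columns with one shared permutation (drawn under a
#' group-and-iteration-specific sub-seed), re-scores the test set and
#' records the performance metric. Reports the mean permuted performance,
#' the performance difference (original minus mean permuted) and an add-one
#' empirical p-value,
#' `(#\{permuted >= original\} + 1) / (nperm + 1)` for metrics where larger
#' is better (inequality reversed otherwise), so p-values are never zero
#' and lie exactly on the lattice `k / (nperm + 1)`. The caller's test data
#' are never mutated.
#'
#' @param model An `ml_model` handle.
#' @param test An [ml_dataset] with the held-out samples.
#' @param groups Named list mapping a kept feature name to all member
#'   feature names permuted together (from
#'   [preprocess_data()]`$correlated_groups`); `NULL` treats every feature
#'   as its own group.
#' @param metric Performance metric; defaults to the outcome kind's default.
#' @param nperm Number of permutations per group (>= 1).
#' @param seed Integer seed.
#' @param positive Positive-class label for binary outcomes.
#' @return An object of class `ml_importance`: a data.frame with columns
#'   `group_name`, `members` (semicolon-joined), `perf_metric` (mean
#'   permuted performance), `perf_metric_diff`, `pvalue`, `nperm` and
#'   `metric`, sorted by decreasing `perf_metric_diff` (name tie-break).
#'   The unpermuted test performance is in `attr(, "original_metric")`.
#' @export
permutation_importance <- function(model, test, groups = NULL, metric = NULL,
                                   nperm = 100, seed = 1, positive = NULL) {
  if (nperm < 1) stop("nperm must be >= 1", call. = FALSE)
  x <- dataset_matrix(test)
  truth <- dataset_outcome(test)
  kind <- model$outcome_kind
  if (is.null(metric)) metric <- default_metric(kind)
  check_metric(metric, kind)
  if (is.null(positive)) positive <- model$positive
  if (is.null(groups)) {
    groups <- stats::setNames(as.list(colnames(x)), colnames(x))
  }
  # members collapsed away during preprocessing are absent from the model's
  # feature space; permuting the kept representative permutes the group.
  # A group with NO member present is a caller error.
  for (g in names(groups)) {
    present <- intersect(groups[[g]], colnames(x))
    if (length(present) == 0L) {
      stop(sprintf("group member(s) not found in test data: %s",
                   paste(groups[[g]], collapse = ", ")), call. = FALSE)
    }
  }
  maximize <- metric_maximize(metric)
  orig <- eval_metric(metric, score_model(model, x), truth, kind,
                      positive = positive)
  n <- nrow(x)
  records <- lapply(names(groups), function(g) {
    members <- groups[[g]]
    permute_cols <- intersect(members, colnames(x))
    vals <- vapply(seq_len(nperm), function(i) {
      perm <- with_seed(derive_seed(seed, "perm", g, i), sample.int(n))
      xp <- x
      xp[, permute_cols] <- x[perm, permute_cols, drop = FALSE]
      eval_metric(metric, score_model(model, xp), truth, kind,
                  positive = positive)
    }, 0)
    extreme <- if (maximize) sum(vals >= orig) else sum(vals <= orig)
    data.frame(
      group_name = g,
      members = paste(members, collapse = ";"),
      perf_metric = mean(vals),
      perf_metric_diff = orig - mean(vals),
      pvalue = (extreme + 1) / (nperm + 1),
      nperm = nperm,
      metric = metric,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, records)
  out <- out[order(-out$perf_metric_diff, out$group_name), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "original_metric") <- orig
  class(out) <- c("ml_importance", "data.frame")
  out
}

#' @export
print.ml_importance <- function(x, ...) {
  cat(sprintf("<ml_importance> %d group(s), metric %s (original = %.4f)\n",
              nrow(x), x$metric[1], attr(x, "original_metric")))
  print.data.frame(utils::head(as.data.frame(x), 10))
  invisible(x)
}
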