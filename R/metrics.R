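# Held-out performance metrics computed from the score/prediction contracts
# only.  AUROC is the Mann-Whitney U statistic scaled to [0,1] (ties count
# one half), which equals the trapezoidal area under the ROC curve when tied
# scores are grouped into a single threshold step.

as_binary_labels <- function(labels, positive = NULL) {
  labels <- as.character(labels)
  lev <- sort(unique(labels[!is.na(labels)]))
  if (length(lev) < 2L) stop("AUROC undefined: labels contain a single class",
                             call. = FALSE)
  if (length(lev) > 2L) stop("binary labels required", call. = FALSE)
  if (is.null(positive)) positive <- lev[2]
  if (!positive %in% lev) stop(sprintf("positive class '%s' not in labels", positive),
                               call. = FALSE)
  labels == positive
}

#' Area under the ROC curve
#'
#' Probability that a randomly chosen positive sample outscores a randomly
#' chosen negative one, with ties counted one half: the Mann-Whitney U
#' statistic divided by `n_pos * n_neg`. Identical to the trapezoidal area
#' under the tie-grouped ROC curve.
#'
#' @param scores Numeric score for the positive class, one per sample.
#' @param labels Binary labels (any two-level vector, or logical).
#' @param positive Positive-class label; defaults to the lexicographically
#'   second level.
#' @return AUROC in `[0, 1]`.
#' @examples
#' auroc(c(0.9, 0.6, 0.4, 0.2), c(1, 0, 1, 0))  # 3 of 4 pairs concordant
#' @export
auroc <- function(scores, labels, positive = NULL) {
  pos <- if (is.logical(labels)) labels else as_binary_labels(labels, positive)
  stopifnot(length(scores) == length(pos))
  if (!any(pos) || all(pos)) stop("AUROC undefined: labels contain a single class",
                                  call. = FALSE)
  r <- rank(scores)  # midranks handle ties as 1/2
  n_pos <- sum(pos)
  n_neg <- sum(!pos)
  u <- sum(r[pos]) - n_pos * (n_pos + 1) / 2
  u / (n_pos * n_neg)
}

# ROC curve with tied scores grouped into one threshold step; starts at
# (0,0) and ends at (1,1), coordinates non-decreasing.
roc_points <- function(scores, labels, positive = NULL) {
  pos <- if (is.logical(labels)) labels else as_binary_labels(labels, positive)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  p <- pos[ord]
  last <- !duplicated(s, fromLast = TRUE)  # end of each tie group
  tp <- cumsum(p)[last]
  fp <- cumsum(!p)[last]
  data.frame(
    fpr = c(0, fp / sum(!pos)),
    tpr = c(0, tp / sum(pos)),
    threshold = c(Inf, s[last])
  )
}

# Precision-recall curve (tie-grouped) and average precision
# AP = sum_i (R_i - R_{i-1}) P_i, whose expectation for a random scorer is
# the positive prevalence.
pr_points <- function(scores, labels, positive = NULL) {
  pos <- if (is.logical(labels)) labels else as_binary_labels(labels, positive)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  p <- pos[ord]
  last <- !duplicated(s, fromLast = TRUE)
  tp <- cumsum(p)[last]
  n_pred <- which(last)
  data.frame(
    recall = c(0, tp / sum(pos)),
    precision = c(1, tp / n_pred),
    threshold = c(Inf, s[last])
  )
}

#' Area under the precision-recall curve
#'
#' Average precision: the sum over threshold steps of precision times the
#' recall increment (no interpolation). For a random scorer this converges
#' to the positive-class prevalence.
#'
#' @inheritParams auroc
#' @return AUPRC in `[0, 1]`.
#' @export
auprc <- function(scores, labels, positive = NULL) {
  pr <- pr_points(scores, labels, positive)
  sum(diff(pr$recall) * pr$precision[-1])
}

rmse <- function(pred, truth) sqrt(mean((pred - truth)^2))
mae <- function(pred, truth) mean(abs(pred - truth))
r_squared <- function(pred, truth) {
  ss_tot <- sum((truth - mean(truth))^2)
  if (ss_tot == 0) return(NA_real_)
  1 - sum((truth - pred)^2) / ss_tot
}

# Mean one-vs-rest AUROC over the classes present in `labels`.
multiclass_auroc <- function(score_matrix, labels) {
  labels <- as.character(labels)
  present <- intersect(colnames(score_matrix), unique(labels))
  mean(vapply(present, function(cl) {
    auroc(score_matrix[, cl], labels == cl)
  }, 0))
}

# ---- tuning-metric registry ---------------------------------------------

METRICS <- list(
  auroc = list(kind = c("binary", "multiclass"), maximize = TRUE),
  auprc = list(kind = "binary", maximize = TRUE),
  accuracy = list(kind = c("binary", "multiclass"), maximize = TRUE),
  rmse = list(kind = "continuous", maximize = FALSE),
  mae = list(kind = "continuous", maximize = FALSE),
  rsq = list(kind = "continuous", maximize = TRUE)
)

default_metric <- function(outcome_kind) {
  if (is_classification(outcome_kind)) "auroc" else "rmse"
}

check_metric <- function(metric, outcome_kind) {
  if (!metric %in% names(METRICS)) {
    stop(sprintf("unknown metric '%s'; available: %s", metric,
                 paste(names(METRICS), collapse = ", ")), call. = FALSE)
  }
  if (!outcome_kind %in% METRICS[[metric]]$kind) {
    stop(sprintf("metric '%s' is undefined for a %s outcome", metric, outcome_kind),
         call. = FALSE)
  }
  metric
}

metric_maximize <- function(metric) METRICS[[metric]]$maximize

# Evaluate a tuning metric from scores.  `scores` follows the score_model()
# contract; `positive` names the positive class for binary outcomes.
eval_metric <- function(metric, scores, truth, outcome_kind, positive = NULL,
                        levels = NULL) {
  if (outcome_kind == "continuous") {
    return(switch(metric,
                  rmse = rmse(scores, truth),
                  mae = mae(scores, truth),
                  rsq = r_squared(scores, truth)))
  }
  truth <- as.character(truth)
  if (outcome_kind == "binary") {
    if (is.null(positive)) positive <- sort(unique(truth))[2]
    ps <- scores[, positive]
    return(switch(metric,
      auroc = auroc(ps, truth == positive),
      auprc = auprc(ps, truth == positive),
      accuracy = {
        neg <- setdiff(colnames(scores), positive)[1]
        mean(ifelse(ps >= 0.5, positive, neg) == truth)
      }))
  }
  # multiclass
  switch(metric,
    auroc = multiclass_auroc(scores, truth),
    accuracy = mean(colnames(scores)[max.col(scores, ties.method = "first")] == truth))
}

#' Held-out performance of a fitted model
#'
#' Scores a fitted model handle on a test set and computes every applicable
#' metric. Binary classification reports AUROC, AUPRC, accuracy, balanced
#' accuracy, F1, sensitivity and specificity (threshold metrics use cutoff
#' 0.5 on the positive-class score) plus ROC and precision-recall curve
#' points; multiclass reports mean one-vs-rest AUROC, accuracy and balanced
#' accuracy; regression reports RMSE, MAE and R-squared.
#'
#' @param model An `ml_model` handle.
#' @param test An [ml_dataset] holding the held-out samples.
#' @param positive Positive-class label for binary outcomes; defaults to the
#'   lexicographically second outcome level.
#' @return An object of class `ml_performance`: list with `metrics` (named
#'   numeric), `roc_points` and `prc_points` (binary only), `n_test` and
#'   `positive`.
#' @export
calc_performance <- function(model, test, positive = NULL) {
  x <- dataset_matrix(test)
  truth <- dataset_outcome(test)
  if (nrow(x) == 0L) stop("test set is empty", call. = FALSE)
  kind <- model$outcome_kind
  sc <- score_model(model, x)

  if (kind == "continuous") {
    perf <- list(
      metrics = c(rmse = rmse(sc, truth), mae = mae(sc, truth),
                  rsq = r_squared(sc, truth)),
      roc_points = NULL, prc_points = NULL,
      n_test = nrow(x), positive = NULL
    )
    return(structure(perf, class = "ml_performance"))
  }

  truth <- as.character(truth)
  if (kind == "binary") {
    lev <- model$levels
    if (is.null(positive)) positive <- model$positive
    neg <- setdiff(lev, positive)[1]
    ps <- sc[, positive]
    pred <- ifelse(ps >= 0.5, positive, neg)
    tp <- sum(pred == positive & truth == positive)
    fp <- sum(pred == positive & truth != positive)
    tn <- sum(pred != positive & truth != positive)
    fn <- sum(pred != positive & truth == positive)
    sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    f1 <- if (is.na(sens) || prec + sens == 0) 0 else 2 * prec * sens / (prec + sens)
    both <- length(unique(truth)) == 2
    metrics <- c(
      auroc = if (both) auroc(ps, truth == positive) else NA_real_,
      auprc = if (both) auprc(ps, truth == positive) else NA_real_,
      accuracy = mean(pred == truth),
      balanced_accuracy = mean(c(sens, spec)),
      f1 = f1, sensitivity = sens, specificity = spec
    )
    if (!both) warning("test set contains a single class; AUROC/AUPRC omitted",
                       call. = FALSE)
    perf <- list(
      metrics = metrics,
      roc_points = if (both) roc_points(ps, truth == positive) else NULL,
      prc_points = if (both) pr_points(ps, truth == positive) else NULL,
      n_test = nrow(x), positive = positive
    )
    return(structure(perf, class = "ml_performance"))
  }

  # multiclass
  pred <- colnames(sc)[max.col(sc, ties.method = "first")]
  classes <- sort(unique(truth))
  recalls <- vapply(classes, function(cl) mean(pred[truth == cl] == cl), 0)
  metrics <- c(
    auroc = multiclass_auroc(sc, truth),
    accuracy = mean(pred == truth),
    balanced_accuracy = mean(recalls)
  )
  structure(list(metrics = metrics, roc_points = NULL, prc_points = NULL,
                 n_test = nrow(x), positive = NULL),
            class = "ml_performance")
}

#' @export
print.ml_performance <- function(x, ...) {
  cat(sprintf("<ml_performance> n_test = %d\n", x$n_test))
  if (!is.null(x$positive)) cat(sprintf("  positive class: %s\n", x$positive))
  m <- x$metrics
  cat(paste0("  ", names(m), " = ", signif(m, 4), collapse = "\n"), "\n")
  invisible(x)
}
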