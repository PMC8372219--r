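# Reproducible train/test partitions: outcome-stratified (the default),
# group-aware (whole batches/sites on one side), or simple random.

new_ml_split <- function(train, test, seed, method, training_frac) {
  structure(
    list(train_indices = sort(train), test_indices = sort(test),
         seed = seed, method = method, training_frac = training_frac),
    class = "ml_split"
  )
}

#' @export
print.ml_split <- function(x, ...) {
  cat(sprintf("<ml_split> %s: %d train / %d test (frac %.3g, seed %d)\n",
              x$method, length(x$train_indices), length(x$test_indices),
              x$training_frac, x$seed))
  invisible(x)
}

# Continuous outcomes are stratified on quartile bins so the outcome
# distribution is preserved on both sides.
stratum_labels <- function(outcome) {
  if (is.numeric(outcome) && length(unique(outcome)) > 10L) {
    breaks <- unique(stats::quantile(outcome, probs = seq(0, 1, 0.25), na.rm = TRUE))
    if (length(breaks) < 2L) breaks <- range(outcome) + c(-1, 1)
    as.character(cut(outcome, breaks = breaks, include.lowest = TRUE))
  } else {
    as.character(outcome)
  }
}

#' Outcome-stratified train/test split
#'
#' Randomly partitions samples into train and test sets while maintaining the
#' distribution of the outcome found in the full dataset: each class c with
#' n_c samples contributes `round(training_frac * n_c)` samples to the
#' training set (round-half-even), drawn uniformly at random under `seed`.
#' If the resulting global training size drifts by more than one sample from
#' `round(training_frac * n)` the largest class is adjusted by one.
#' Continuous outcomes are stratified on quartile bins.
#'
#' @param outcome Per-sample outcome labels (or numeric outcome values).
#' @param training_frac Fraction of samples for the training set, in (0, 1).
#' @param seed Integer seed; identical inputs give identical splits.
#' @return An object of class `ml_split` with sorted `train_indices` and
#'   `test_indices`, `seed`, `method = "stratified"` and `training_frac`.
#' @examples
#' s <- stratified_split(rep(c("healthy", "cancer"), c(60, 40)), 0.8, seed = 1)
#' table(rep(c("healthy", "cancer"), c(60, 40))[s$train_indices])
#' @export
stratified_split <- function(outcome, training_frac, seed) {
  stopifnot(training_frac > 0, training_frac < 1)
  labels <- stratum_labels(outcome)
  if (anyNA(labels)) stop("outcome contains missing values", call. = FALSE)
  n <- length(labels)
  classes <- sort(unique(labels))
  counts <- table(labels)[classes]
  if (any(counts < 2L)) {
    stop(sprintf(
      "outcome class(es) with a single sample (%s); remove them or use simple_split()",
      paste(classes[counts < 2L], collapse = ", ")), call. = FALSE)
  }
  counts_n <- as.numeric(counts)
  n_train_c <- round(training_frac * counts_n)
  target <- round(training_frac * n)
  drift <- sum(n_train_c) - target
  if (abs(drift) > 1) {
    # undo one rounding step in the drift's direction: adjusting a class
    # whose rounding error shares the drift's sign keeps its per-class
    # error within one sample
    err <- n_train_c - training_frac * counts_n
    cand <- which(sign(err) == sign(drift))
    if (length(cand) == 0L) cand <- seq_along(counts_n)
    big <- cand[which.max(counts_n[cand])]
    n_train_c[big] <- min(max(n_train_c[big] - sign(drift), 0), counts_n[big])
  }
  train <- with_seed(derive_seed(seed, "stratified_split"), {
    unlist(lapply(seq_along(classes), function(i) {
      idx <- which(labels == classes[i])
      if (n_train_c[i] <= 0L) return(integer())
      idx[sample.int(length(idx), n_train_c[i])]
    }))
  })
  test <- setdiff(seq_len(n), train)
  if (length(test) == 0L) {
    big <- which.max(counts)
    move <- train[labels[train] == classes[big]][1]
    warning("test set was empty; moving one sample from the largest class",
            call. = FALSE)
    train <- setdiff(train, move)
    test <- move
  }
  if (length(train) == 0L) {
    warning("training set was empty; moving one sample from the largest class",
            call. = FALSE)
    big <- which.max(counts)
    move <- test[labels[test] == classes[big]][1]
    test <- setdiff(test, move)
    train <- move
  }
  new_ml_split(train, test, seed, "stratified", training_frac)
}

#' Group-aware train/test split
#'
#' Assigns whole groups (batches, sites, subjects, ...) to one side of the
#' partition so that no group label ever appears in both train and test —
#' preventing leakage through group structure. Groups are shuffled under
#' `seed` and assigned to the training set until the cumulative sample count
#' first reaches `training_frac * n`; the remaining groups form the test set.
#'
#' @param groups Per-sample group labels; at least two distinct groups.
#' @param training_frac Fraction of samples targeted for training, in (0, 1).
#' @param seed Integer seed.
#' @return An `ml_split` with `method = "grouped"`.
#' @export
grouped_split <- function(groups, training_frac, seed) {
  stopifnot(training_frac > 0, training_frac < 1)
  groups <- as.character(groups)
  if (anyNA(groups)) stop("group labels contain missing values", call. = FALSE)
  n <- length(groups)
  levels <- sort(unique(groups))
  if (length(levels) < 2L) {
    stop("grouped_split() requires at least 2 distinct groups", call. = FALSE)
  }
  order <- with_seed(derive_seed(seed, "grouped_split"),
                     sample(levels, length(levels)))
  sizes <- table(groups)[order]
  k <- which(cumsum(as.numeric(sizes)) >= training_frac * n)[1]
  if (is.na(k)) k <- length(order)
  if (k == length(order)) {
    warning("all groups were assigned to training; moving the last group to test",
            call. = FALSE)
    k <- length(order) - 1L
  }
  train_groups <- order[seq_len(k)]
  train <- which(groups %in% train_groups)
  test <- which(!groups %in% train_groups)
  new_ml_split(train, test, seed, "grouped", training_frac)
}

#' Simple random train/test split
#'
#' Ignores outcome and group structure: `round(training_frac * n)` samples are
#' drawn uniformly at random into the training set. Mainly useful when a
#' class has too few samples to stratify.
#'
#' @param n Number of samples.
#' @param training_frac Fraction for the training set, in (0, 1).
#' @param seed Integer seed.
#' @return An `ml_split` with `method = "simple"`.
#' @export
simple_split <- function(n, training_frac, seed) {
  stopifnot(n >= 2, training_frac > 0, training_frac < 1)
  k <- min(max(round(training_frac * n), 1L), n - 1L)
  train <- with_seed(derive_seed(seed, "simple_split"), sample.int(n, k))
  new_ml_split(train, setdiff(seq_len(n), train), seed, "simple", training_frac)
}
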