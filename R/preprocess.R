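# Preprocessing: constant-feature removal, one-hot encoding of categorical
# features, centring/scaling of continuous features, near-zero-variance
# filtering and collapsing of perfectly correlated features, with complete
# bookkeeping of what happened to every original feature.
#
# Statistics are fitted on the FULL dataset before train/test splitting
# (fidelity to the pipeline this package implements); the methods vignette
# documents the mild leakage this implies for the scaling parameters.

is_binary_col <- function(x) {
  v <- x[!is.na(x)]
  is.numeric(x) && length(v) > 0 && all(v %in% c(0, 1))
}

#' Remove constant features
#'
#' Drops every feature whose non-missing values are all identical (including
#' all-missing features). This is the mandatory zero-variance base case of
#' variance filtering and always runs first.
#'
#' @param dataset An [ml_dataset].
#' @return A list with `dataset` (features removed) and `removed`
#'   (character vector of dropped feature names).
#' @export
remove_constant_features <- function(dataset) {
  feats <- dataset_features(dataset)
  constant <- vapply(feats, function(x) {
    v <- unique(x[!is.na(x)])
    length(v) <= 1L
  }, TRUE)
  removed <- names(feats)[constant]
  keep <- setdiff(dataset$feature_names, removed)
  if (length(keep) == 0L) stop("no features remain after removing constant features",
                               call. = FALSE)
  dataset$table <- dataset$table[c(dataset$outcome_name, keep)]
  dataset$feature_names <- keep
  list(dataset = dataset, removed = removed)
}

#' Encode categorical features as binary indicators
#'
#' Re-factors each categorical feature into numeric indicator columns. A
#' feature with L > 2 levels becomes L columns named `<feature>_<level>`; a
#' feature with exactly 2 levels becomes a single column named after the
#' lexicographically second level, holding 1 for that level and 0 otherwise.
#' A missing categorical value yields `NA` in every derived indicator.
#'
#' @param dataset An [ml_dataset].
#' @return A list with `dataset` (all features numeric) and `name_map`, a
#'   named list mapping each original feature to its derived column names
#'   (continuous features map to themselves).
#' @export
encode_categorical <- function(dataset) {
  feats <- dataset_features(dataset)
  existing <- c(dataset$outcome_name, names(feats))
  out_cols <- list()
  name_map <- list()
  for (nm in names(feats)) {
    x <- feats[[nm]]
    if (is.numeric(x)) {
      out_cols[[nm]] <- x
      name_map[[nm]] <- nm
      next
    }
    x <- as.character(x)
    levels <- sort(unique(x[!is.na(x)]))
    if (length(levels) == 2L) {
      derived <- paste0(nm, "_", levels[2])
      cols <- list(as.numeric(x == levels[2]))
    } else {
      derived <- paste0(nm, "_", levels)
      cols <- lapply(levels, function(l) as.numeric(x == l))
    }
    # missing propagates into every indicator of this feature
    for (i in seq_along(cols)) cols[[i]][is.na(x)] <- NA_real_
    # deterministic suffixing on collision with an existing column name
    taken <- c(existing, names(out_cols))
    for (i in seq_along(derived)) {
      if (derived[i] %in% taken) {
        k <- 2L
        while (paste0(derived[i], "_", k) %in% taken) k <- k + 1L
        warning(sprintf("encoded name '%s' collides with an existing column; using '%s_%d'",
                        derived[i], derived[i], k), call. = FALSE)
        derived[i] <- paste0(derived[i], "_", k)
      }
      taken <- c(taken, derived[i])
    }
    names(cols) <- derived
    out_cols <- c(out_cols, cols)
    name_map[[nm]] <- derived
  }
  tab <- dataset$table[dataset$outcome_name]
  for (nm in names(out_cols)) tab[[nm]] <- out_cols[[nm]]
  dataset$table <- tab
  dataset$feature_names <- names(out_cols)
  list(dataset = dataset, name_map = name_map)
}

#' Centre and scale continuous features
#'
#' Replaces each continuous feature x by (x - mean) / sd, with mean and
#' sample sd (denominator n - 1) computed over non-missing values; missing
#' entries are first imputed with the pre-normalisation median. Binary 0/1
#' columns (including one-hot indicators) are never normalised, which also
#' makes the transformation idempotent. A feature whose sd is 0 at this
#' point is dropped with a warning.
#'
#' @param dataset An [ml_dataset] whose features are numeric.
#' @param method `"center_scale"` or `"none"` (identity).
#' @return A list with `dataset` and `params`, a data.frame with one row per
#'   normalised feature (`feature`, `mean`, `sd`, `median`).
#' @export
normalize_continuous <- function(dataset, method = c("center_scale", "none")) {
  method <- match.arg(method)
  empty <- data.frame(feature = character(), mean = numeric(),
                      sd = numeric(), median = numeric(),
                      stringsAsFactors = FALSE)
  if (method == "none") return(list(dataset = dataset, params = empty))
  feats <- dataset_features(dataset)
  params <- list()
  dropped <- character()
  for (nm in names(feats)) {
    x <- feats[[nm]]
    if (!is.numeric(x)) stop(sprintf("feature '%s' is not numeric", nm), call. = FALSE)
    if (is_binary_col(x)) next
    med <- stats::median(x, na.rm = TRUE)
    x[is.na(x)] <- med
    m <- mean(x)
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0) {
      warning(sprintf("feature '%s' has zero variance after imputation; dropping it", nm),
              call. = FALSE)
      dropped <- c(dropped, nm)
      next
    }
    dataset$table[[nm]] <- (x - m) / s
    params[[nm]] <- data.frame(feature = nm, mean = m, sd = s, median = med,
                               stringsAsFactors = FALSE)
  }
  if (length(dropped)) {
    keep <- setdiff(dataset$feature_names, dropped)
    dataset$table <- dataset$table[c(dataset$outcome_name, keep)]
    dataset$feature_names <- keep
  }
  params <- if (length(params)) do.call(rbind, c(params, make.row.names = FALSE)) else empty
  list(dataset = dataset, params = params)
}

# Frequency-ratio / percent-unique statistics for one numeric vector.
nzv_stats <- function(x) {
  x <- x[!is.na(x)]
  counts <- sort(tabulate(match(x, unique(x))), decreasing = TRUE)
  ratio <- if (length(counts) < 2L) Inf else counts[1] / counts[2]
  list(freq_ratio = ratio,
       pct_unique = 100 * length(counts) / length(x))
}

#' Remove near-zero-variance features
#'
#' A feature is removed iff its frequency ratio (count of the most common
#' value over the count of the second most common) is at least `freq_cut`
#' AND its percentage of distinct values is at most `unique_cut`. A feature
#' with a single distinct value has an infinite frequency ratio and is
#' always removed.
#'
#' @param dataset An [ml_dataset] with numeric features.
#' @param freq_cut Frequency-ratio cutoff (default 95/5 = 19).
#' @param unique_cut Percent-unique cutoff (default 10).
#' @return A list with `dataset` and `removed` (dropped feature names).
#' @export
remove_near_zero_variance <- function(dataset, freq_cut = 95 / 5, unique_cut = 10) {
  feats <- dataset_features(dataset)
  nzv <- vapply(feats, function(x) {
    s <- nzv_stats(x)
    s$freq_ratio >= freq_cut && s$pct_unique <= unique_cut
  }, TRUE)
  removed <- names(feats)[nzv]
  keep <- setdiff(dataset$feature_names, removed)
  if (length(keep) == 0L) stop("no features remain after near-zero-variance filtering",
                               call. = FALSE)
  dataset$table <- dataset$table[c(dataset$outcome_name, keep)]
  dataset$feature_names <- keep
  list(dataset = dataset, removed = removed)
}

#' Collapse perfectly correlated features
#'
#' Builds a graph over features with an edge wherever the absolute Pearson
#' correlation reaches `corr_threshold` (with tolerance 1e-10 when the
#' threshold is 1, so exact copies survive floating point) and keeps, within
#' each connected component, the feature that comes first in the original
#' column order. The returned groups are what the permutation-importance
#' module permutes jointly.
#'
#' @param dataset An [ml_dataset] with numeric, complete (no missing)
#'   features.
#' @param corr_threshold Absolute correlation in `[0, 1]`; default 1 keeps
#'   only exact (up to sign) linear copies together.
#' @return A list with `dataset` and `groups`, a named list mapping each
#'   kept feature to all members of its component (itself included).
#' @export
collapse_correlated <- function(dataset, corr_threshold = 1) {
  stopifnot(corr_threshold >= 0, corr_threshold <= 1)
  feats <- dataset_features(dataset)
  p <- ncol(feats)
  thr <- if (corr_threshold >= 1) 1 - 1e-10 else corr_threshold
  groups <- stats::setNames(as.list(names(feats)), names(feats))
  if (p >= 2L) {
    cm <- suppressWarnings(abs(stats::cor(as.matrix(feats))))
    cm[is.na(cm)] <- 0
    adj <- cm >= thr
    diag(adj) <- FALSE
    comp <- rep(NA_integer_, p)
    cid <- 0L
    for (i in seq_len(p)) {
      if (!is.na(comp[i])) next
      cid <- cid + 1L
      queue <- i
      comp[i] <- cid
      while (length(queue)) {
        v <- queue[[1]]; queue <- queue[-1]
        nb <- which(adj[v, ] & is.na(comp))
        comp[nb] <- cid
        queue <- c(queue, nb)
      }
    }
    groups <- lapply(split(seq_len(p), comp), function(ix) names(feats)[sort(ix)])
    # representative: first member in original column order
    names(groups) <- vapply(groups, `[[`, "", 1L)
    groups <- groups[order(match(names(groups), names(feats)))]
  }
  keep <- names(groups)
  dataset$table <- dataset$table[c(dataset$outcome_name, keep)]
  dataset$feature_names <- keep
  list(dataset = dataset, groups = groups)
}

#' Preprocess a dataset for model training
#'
#' Applies, in order: constant-feature removal, one-hot encoding of
#' categorical features, median imputation plus centring/scaling of
#' continuous features (indicator missing values are imputed as 0 with a
#' warning), near-zero-variance filtering, and collapsing of perfectly
#' correlated features. The result carries complete bookkeeping: every
#' original feature is accounted for as surviving (possibly renamed by the
#' encoding), removed, or collapsed into a kept representative. Applying
#' `preprocess_data()` to its own output changes nothing.
#'
#' @param dataset An [ml_dataset].
#' @param normalize_method `"center_scale"` (default) or `"none"`.
#' @param remove_variance `"near_zero"` (default; frequency-ratio filter),
#'   `"non_zero_only"` or `"none"` (both keep only the mandatory
#'   constant-feature removal).
#' @param collapse_correlated Collapse perfectly correlated features
#'   (default `TRUE`).
#' @param corr_threshold Absolute-correlation threshold for collapsing
#'   (default 1).
#' @param freq_cut,unique_cut Near-zero-variance cutoffs; see
#'   [remove_near_zero_variance()].
#' @return An object of class `ml_preprocess`: a list with `dataset` (the
#'   transformed, all-numeric [ml_dataset]), `removed_features` (list with
#'   elements `constant` and `near_zero_variance`), `correlated_groups`
#'   (kept feature -> members), `normalization_params`, `feature_map`
#'   (original feature -> derived column names) and `config`.
#' @examples
#' d <- ml_dataset(data.frame(dx = rep(c("h", "c"), 5),
#'                            otu1 = rnorm(10), site = rep(c("a", "b"), 5)), "dx")
#' p <- preprocess_data(d)
#' p$dataset$feature_names
#' @export
preprocess_data <- function(dataset,
                            normalize_method = c("center_scale", "none"),
                            remove_variance = c("near_zero", "non_zero_only", "none"),
                            collapse_correlated = TRUE,
                            corr_threshold = 1,
                            freq_cut = 95 / 5,
                            unique_cut = 10) {
  normalize_method <- match.arg(normalize_method)
  remove_variance <- match.arg(remove_variance)
  stopifnot(freq_cut >= 1, unique_cut >= 0, unique_cut <= 100)

  st1 <- remove_constant_features(dataset)
  st2 <- encode_categorical(st1$dataset)

  # indicator columns derived from a missing categorical value: impute 0
  ds <- st2$dataset
  derived <- setdiff(unlist(st2$name_map), names(st2$name_map))
  na_ind <- derived[vapply(derived, function(nm) anyNA(ds$table[[nm]]), TRUE)]
  if (length(na_ind)) {
    warning(sprintf("imputing missing indicator values as 0 in: %s",
                    paste(unique(sub("_[^_]*$", "", na_ind)), collapse = ", ")),
            call. = FALSE)
    for (nm in na_ind) {
      x <- ds$table[[nm]]
      x[is.na(x)] <- 0
      ds$table[[nm]] <- x
    }
  }

  st3 <- normalize_continuous(ds, normalize_method)
  # method "none" leaves missing values in place; impute medians so the
  # downstream stages (and models) see complete data
  ds <- st3$dataset
  for (nm in ds$feature_names) {
    x <- ds$table[[nm]]
    if (anyNA(x)) {
      x[is.na(x)] <- stats::median(x, na.rm = TRUE)
      ds$table[[nm]] <- x
    }
  }

  nzv_removed <- character()
  if (remove_variance == "near_zero") {
    st4 <- remove_near_zero_variance(ds, freq_cut = freq_cut, unique_cut = unique_cut)
    ds <- st4$dataset
    nzv_removed <- st4$removed
  }

  groups <- stats::setNames(as.list(ds$feature_names), ds$feature_names)
  if (isTRUE(collapse_correlated)) {
    st5 <- collapse_correlated(ds, corr_threshold = corr_threshold)
    ds <- st5$dataset
    groups <- st5$groups
  }

  structure(
    list(
      dataset = ds,
      removed_features = list(constant = st1$removed,
                              near_zero_variance = nzv_removed),
      correlated_groups = groups,
      normalization_params = st3$params,
      feature_map = st2$name_map,
      config = list(normalize_method = normalize_method,
                    remove_variance = remove_variance,
                    collapse_correlated = collapse_correlated,
                    corr_threshold = corr_threshold,
                    freq_cut = freq_cut, unique_cut = unique_cut)
    ),
    class = "ml_preprocess"
  )
}

#' @export
print.ml_preprocess <- function(x, ...) {
  cat(sprintf("<ml_preprocess> %d samples x %d features after preprocessing\n",
              nrow(x$dataset$table), length(x$dataset$feature_names)))
  cat(sprintf("  removed: %d constant, %d near-zero-variance\n",
              length(x$removed_features$constant),
              length(x$removed_features$near_zero_variance)))
  multi <- Filter(function(g) length(g) > 1, x$correlated_groups)
  cat(sprintf("  correlated groups (>1 member): %d\n", length(multi)))
  invisible(x)
}
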