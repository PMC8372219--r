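# Synthetic feature tables with the statistical structure every pipeline
# stage assumes: planted logistic/linear effects, exact affine-copy
# correlated pairs, near-zero-variance and constant features, categorical
# features, MCAR missingness and optional group labels.  The generator
# returns the full generating truth so recovery can be tested.

#' Specify a synthetic dataset
#'
#' @param n_samples Number of samples (default 200).
#' @param n_continuous Number of standard-normal continuous features
#'   (default 10).
#' @param n_categorical Number of categorical features, each with 3-5 levels
#'   (default 0).
#' @param n_informative Number of continuous features given nonzero planted
#'   coefficients (default 5).
#' @param effect_sizes Planted coefficients: log-odds for a binary outcome,
#'   linear coefficients otherwise; recycled over the informative features
#'   (default 1).
#' @param n_correlated_pairs Number of feature pairs where the second member
#'   is an exact affine copy (2x + 3) of the first, guaranteeing |r| = 1
#'   (default 0).
#' @param n_nzv Number of near-zero-variance features: one dominant value in
#'   more than 95% of rows and at most 10% distinct values (default 0).
#' @param n_constant Number of constant features (default 0).
#' @param missing_rate MCAR missingness fraction in `[0, 1)`, applied to
#'   feature cells except correlated-pair columns (so the exact-copy
#'   guarantee survives imputation; default 0).
#' @param outcome_kind `"binary"` (logistic model, intercept 0 for ~50%
#'   prevalence), `"multiclass"` (3-class softmax) or `"continuous"`
#'   (linear model with unit-variance noise).
#' @param n_groups Optional number of group labels for grouped splitting.
#' @param seed Integer seed; generation is fully deterministic.
#' @return An object of class `ml_synth_spec`.
#' @export
synth_spec <- function(n_samples = 200, n_continuous = 10, n_categorical = 0,
                       n_informative = 5, effect_sizes = 1,
                       n_correlated_pairs = 0, n_nzv = 0, n_constant = 0,
                       missing_rate = 0, outcome_kind = "binary",
                       n_groups = NULL, seed = 1) {
  outcome_kind <- match.arg(outcome_kind, OUTCOME_KINDS)
  stopifnot(n_samples >= 4, n_continuous >= 0, n_categorical >= 0,
            n_informative >= 0, n_correlated_pairs >= 0, n_nzv >= 0,
            n_constant >= 0, missing_rate >= 0, missing_rate < 1)
  if (n_informative > n_continuous + n_categorical) {
    stop("n_informative exceeds the number of continuous + categorical features",
         call. = FALSE)
  }
  if (n_informative > n_continuous) {
    stop("informative effects are planted on continuous features; increase n_continuous",
         call. = FALSE)
  }
  if (n_continuous + n_categorical + n_correlated_pairs == 0) {
    stop("the spec generates no informative or noise features", call. = FALSE)
  }
  structure(
    list(n_samples = n_samples, n_continuous = n_continuous,
         n_categorical = n_categorical, n_informative = n_informative,
         effect_sizes = effect_sizes, n_correlated_pairs = n_correlated_pairs,
         n_nzv = n_nzv, n_constant = n_constant, missing_rate = missing_rate,
         outcome_kind = outcome_kind, n_groups = n_groups, seed = seed),
    class = "ml_synth_spec"
  )
}

#' Generate a synthetic dataset from a specification
#'
#' @param spec An [ml_synth_spec][synth_spec()].
#' @return A list with `dataset` (an [ml_dataset]) and `truth`, a list
#'   recording every planted coefficient and structural feature:
#'   `coefficients` (named, one per continuous feature), `informative`,
#'   `correlated_groups`, `nzv`, `constant`, `outcome_kind` and
#'   `prevalence` (binary only).
#' @examples
#' sim <- generate_dataset(synth_spec(n_constant = 2, n_correlated_pairs = 3))
#' sim$truth$correlated_groups
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "ml_synth_spec"))
  n <- spec$n_samples
  with_seed(derive_seed(spec$seed, "synth"), {
    cols <- list()
    no_missing <- character()  # columns protected from MCAR masking

    beta <- numeric(spec$n_continuous)
    if (spec$n_informative > 0) {
      beta[seq_len(spec$n_informative)] <-
        rep_len(spec$effect_sizes, spec$n_informative)
    }
    xc <- NULL
    if (spec$n_continuous > 0) {
      xc <- matrix(stats::rnorm(n * spec$n_continuous), nrow = n)
      colnames(xc) <- paste0("x", seq_len(spec$n_continuous))
      for (j in seq_len(ncol(xc))) cols[[colnames(xc)[j]]] <- xc[, j]
    }
    names(beta) <- if (spec$n_continuous > 0) colnames(xc) else character()

    eta <- if (is.null(xc)) rep(0, n) else as.numeric(xc %*% beta)
    outcome <- switch(spec$outcome_kind,
      binary = c("neg", "pos")[stats::rbinom(n, 1, stats::plogis(eta)) + 1],
      multiclass = {
        s <- cbind(rep(0, n), eta, -eta)
        p <- exp(s - apply(s, 1, max))
        p <- p / rowSums(p)
        vapply(seq_len(n), function(i) {
          sample(c("classA", "classB", "classC"), 1, prob = p[i, ])
        }, "")
      },
      continuous = eta + stats::rnorm(n)
    )

    for (j in seq_len(spec$n_categorical)) {
      L <- sample(3:5, 1)
      cols[[paste0("cat", j)]] <- sample(paste0("l", seq_len(L)), n, replace = TRUE)
    }

    corr_groups <- list()
    for (j in seq_len(spec$n_correlated_pairs)) {
      base <- stats::rnorm(n)
      a <- paste0("corr", j, "_a")
      b <- paste0("corr", j, "_b")
      cols[[a]] <- base
      cols[[b]] <- 2 * base + 3  # exact affine copy: |r| = 1 by construction
      corr_groups[[a]] <- c(a, b)
      no_missing <- c(no_missing, a, b)
    }

    nzv_names <- character()
    for (j in seq_len(spec$n_nzv)) {
      m <- max(1L, ceiling(0.03 * n))
      v <- numeric(n)
      v[sample.int(n, m)] <- sample(1:3, m, replace = TRUE)
      nm <- paste0("nzv", j)
      cols[[nm]] <- v
      nzv_names <- c(nzv_names, nm)
    }

    const_names <- paste0("const", seq_len(spec$n_constant))
    for (nm in const_names) cols[[nm]] <- rep(1, n)

    tab <- data.frame(outcome = outcome, stringsAsFactors = FALSE)
    for (nm in names(cols)) tab[[nm]] <- cols[[nm]]

    if (spec$missing_rate > 0) {
      maskable <- setdiff(names(cols), no_missing)
      for (nm in maskable) {
        miss <- stats::runif(n) < spec$missing_rate
        tab[[nm]][miss] <- NA
      }
    }

    group_labels <- NULL
    if (!is.null(spec$n_groups)) {
      k <- spec$n_groups
      stopifnot(k >= 2, k <= n)
      # every group label occurs at least once
      g <- c(paste0("g", seq_len(k)),
             sample(paste0("g", seq_len(k)), n - k, replace = TRUE))
      group_labels <- g[sample.int(n)]
      tab$group <- group_labels
    }

    dataset <- ml_dataset(tab, "outcome",
                          group_column = if (is.null(group_labels)) NULL else "group",
                          outcome_kind = spec$outcome_kind)
    truth <- list(
      coefficients = beta,
      informative = names(beta)[beta != 0],
      correlated_groups = corr_groups,
      nzv = nzv_names,
      constant = const_names,
      outcome_kind = spec$outcome_kind,
      prevalence = if (spec$outcome_kind == "binary") mean(outcome == "pos") else NULL
    )
    list(dataset = dataset, truth = truth)
  })
}
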