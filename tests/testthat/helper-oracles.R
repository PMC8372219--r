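# Independent brute-force oracles and random-input generators used across
# the suite.  Oracles are deliberately naive (pairwise loops, explicit
# counting) and share no code with the implementation they check.

`%||%` <- function(a, b) if (is.null(a)) b else a

# AUROC by explicit enumeration of all positive/negative pairs.
oracle_auroc <- function(scores, pos) {
  total <- 0
  hits <- 0
  for (i in which(pos)) {
    for (j in which(!pos)) {
      total <- total + 1
      if (scores[i] > scores[j]) hits <- hits + 1
      else if (scores[i] == scores[j]) hits <- hits + 0.5
    }
  }
  hits / total
}

# Near-zero-variance decision by explicit frequency counting.
oracle_nzv <- function(x, freq_cut, unique_cut) {
  x <- x[!is.na(x)]
  counts <- sort(table(as.character(x)), decreasing = TRUE)
  ratio <- if (length(counts) < 2) Inf else as.numeric(counts[1]) / as.numeric(counts[2])
  pct <- 100 * length(counts) / length(x)
  ratio >= freq_cut && pct <= unique_cut
}

# Correlated components by pairwise test + transitive closure.
oracle_corr_groups <- function(df, threshold = 1) {
  nms <- names(df)
  thr <- if (threshold >= 1) 1 - 1e-10 else threshold
  comp <- as.list(nms)
  names(comp) <- nms
  repeat {
    merged <- FALSE
    for (i in seq_along(comp)) {
      if (is.null(comp[[i]])) next
      for (j in seq_along(comp)) {
        if (i == j || is.null(comp[[j]])) next
        link <- any(vapply(comp[[i]], function(a) {
          any(vapply(comp[[j]], function(b) {
            r <- suppressWarnings(cor(df[[a]], df[[b]]))
            !is.na(r) && abs(r) >= thr
          }, TRUE))
        }, TRUE))
        if (link) {
          comp[[i]] <- sort(unique(c(comp[[i]], comp[[j]])))
          comp[j] <- list(NULL)
          merged <- TRUE
        }
      }
    }
    if (!merged) break
  }
  comp <- Filter(Negate(is.null), comp)
  # members and representatives ordered by original column position
  comp <- lapply(comp, function(g) g[order(match(g, nms))])
  out <- comp
  names(out) <- vapply(comp, `[[`, "", 1L)
  out[order(match(names(out), nms))]
}

# Random mixed-type table with a binary outcome; returns an ml_dataset.
random_mixed_dataset <- function(seed, n = NULL, p = NULL) {
  set.seed(seed)
  if (is.null(n)) n <- sample(20:200, 1)
  if (is.null(p)) p <- sample(3:50, 1)
  tab <- data.frame(dx = sample(c("h", "d"), n, replace = TRUE, prob = c(0.6, 0.4)),
                    stringsAsFactors = FALSE)
  while (length(unique(tab$dx)) < 2) tab$dx <- sample(c("h", "d"), n, replace = TRUE)
  for (j in seq_len(p)) {
    kind <- sample(c("cont", "cat", "const", "nzv", "copy", "int"), 1,
                   prob = c(0.4, 0.2, 0.1, 0.1, 0.1, 0.1))
    nm <- paste0("f", j)
    tab[[nm]] <- switch(kind,
      cont = rnorm(n),
      int = sample(0:5, n, replace = TRUE),
      cat = sample(paste0("l", seq_len(sample(2:4, 1))), n, replace = TRUE),
      const = rep(sample(c(1, 7), 1), n),
      nzv = { v <- numeric(n); k <- max(1, round(0.02 * n))
              v[sample(n, k)] <- sample(1:2, k, replace = TRUE); v },
      copy = if (j > 1 && is.numeric(tab[[paste0("f", j - 1)]])) {
               3 * tab[[paste0("f", j - 1)]] - 1
             } else rnorm(n)
    )
  }
  # sprinkle some missingness into a random continuous column
  numcols <- names(tab)[vapply(tab, is.numeric, TRUE)]
  if (length(numcols) && runif(1) < 0.3) {
    nm <- sample(numcols, 1)
    miss <- sample(n, max(1, round(0.05 * n)))
    tab[[nm]][miss] <- NA
  }
  tryCatch(ml_dataset(tab, "dx"), error = function(e) NULL)
}

# A dataset of numeric features with a planted logistic signal.
planted_binary <- function(seed, n = 200, p = 10, n_informative = 5, effect = 2) {
  generate_dataset(synth_spec(n_samples = n, n_continuous = p,
                              n_informative = n_informative,
                              effect_sizes = effect, seed = seed))
}
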