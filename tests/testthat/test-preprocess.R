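# Preprocessing stages: each stage against its brute-force oracle, plus the
# composed pipeline's bookkeeping, idempotence and row-preservation
# invariants.

make_ds <- function(...) {
  cols <- list(...)
  n <- length(cols[[1]])
  ml_dataset(data.frame(dx = rep(c("h", "d"), length.out = n), cols,
                        stringsAsFactors = FALSE), "dx")
}

test_that("constant features are removed, including constants over non-missing values", {
  d <- make_ds(a = c(5, 5, 5, 5), b = c(5, 5, 5, 6), c = c(5, NA, 5, 5))
  st <- remove_constant_features(d)
  expect_setequal(st$removed, c("a", "c"))
  expect_equal(st$dataset$feature_names, "b")
  d2 <- make_ds(a = c(1, 1, 1, 1))
  expect_error(remove_constant_features(d2), "no features remain")
})

test_that("categorical features are one-hot encoded; two levels give one column", {
  d <- make_ds(site = c("a", "a", "b", "b", "c", "c"), x = rnorm(6))
  st <- encode_categorical(d)
  expect_equal(st$dataset$table$site_a, c(1, 1, 0, 0, 0, 0))
  expect_equal(st$dataset$table$site_b, c(0, 0, 1, 1, 0, 0))
  expect_equal(st$dataset$table$site_c, c(0, 0, 0, 0, 1, 1))
  expect_equal(st$name_map$site, c("site_a", "site_b", "site_c"))
  expect_equal(st$name_map$x, "x")

  d2 <- make_ds(sex = c("f", "m", "f", "m"))
  st2 <- encode_categorical(d2)
  expect_equal(st2$dataset$feature_names, "sex_m")
  expect_equal(st2$dataset$table$sex_m, c(0, 1, 0, 1))
})

test_that("missing categorical values propagate into every indicator", {
  d <- make_ds(f = c("a", NA, "b", "c", "a", "b"))
  st <- encode_categorical(d)
  for (col in st$name_map$f) {
    expect_true(is.na(st$dataset$table[[col]][2]))
    expect_false(anyNA(st$dataset$table[[col]][-2]))
  }
})

test_that("derived indicator name collisions are suffixed deterministically", {
  d <- make_ds(f = c("a", "b", "a", "b"), f_b = rnorm(4))
  expect_warning(st <- encode_categorical(d), "collides")
  expect_true("f_b_2" %in% st$dataset$feature_names)
})

test_that("centring/scaling matches the closed form and imputes medians", {
  d <- make_ds(x = c(1, 2, 3), y = c(10, NA, 20))
  st <- normalize_continuous(d, "center_scale")
  expect_equal(st$dataset$table$x, c(-1, 0, 1))
  # y median-imputes to (10,15,20) then z-scores
  expect_equal(st$dataset$table$y, (c(10, 15, 20) - 15) / sd(c(10, 15, 20)))
  expect_equal(st$params$median[st$params$feature == "y"], 15)

  none <- normalize_continuous(d, "none")
  expect_equal(none$dataset$table, d$table)
  expect_equal(nrow(none$params), 0L)
})

test_that("binary 0/1 columns are never normalised", {
  d <- make_ds(ind = c(0, 1, 0, 1), x = c(1, 2, 3, 4))
  st <- normalize_continuous(d, "center_scale")
  expect_equal(st$dataset$table$ind, c(0, 1, 0, 1))
  expect_false("ind" %in% st$params$feature)
})

test_that("scaling agrees with base scale() on random data", {
  set.seed(7)
  d <- make_ds(x = rnorm(50), y = runif(50))
  st <- normalize_continuous(d, "center_scale")
  expect_equal(st$dataset$table$x, as.numeric(scale(d$table$x)))
  expect_equal(st$dataset$table$y, as.numeric(scale(d$table$y)))
})

test_that("near-zero-variance rule matches the frequency-count definition", {
  x <- c(rep(0, 99), 1)                       # ratio 99 >= 19, unique 2% <= 10
  d <- make_ds(a = x, b = rep(c(0, 1), 50), c = seq_len(100))
  st <- remove_near_zero_variance(d)
  expect_equal(st$removed, "a")               # b: ratio 1; c: 100% unique
  expect_setequal(st$dataset$feature_names, c("b", "c"))
})

test_that("near-zero-variance filter equals the brute-force oracle on random tables", {
  for (seed in 1:25) {
    set.seed(seed)
    n <- sample(20:150, 1)
    p <- sample(3:12, 1)
    cols <- lapply(seq_len(p), function(j) {
      k <- sample(c(1, 2, 3, n), 1)
      sample(seq_len(k), n, replace = TRUE)
    })
    names(cols) <- paste0("f", seq_len(p))
    d <- do.call(make_ds, cols)
    expected <- names(cols)[vapply(cols, oracle_nzv, TRUE,
                                   freq_cut = 19, unique_cut = 10)]
    if (length(expected) == p) next  # implementation errors when none remain
    st <- remove_near_zero_variance(d, freq_cut = 19, unique_cut = 10)
    expect_setequal(st$removed, expected)
  }
})

test_that("near-zero-variance agrees with caret away from the cutoff boundary", {
  skip_if_not_installed("caret")
  set.seed(11)
  for (rep in 1:10) {
    n <- 80
    cols <- lapply(1:8, function(j) sample(seq_len(sample(c(2, 3, n), 1)), n,
                                           replace = TRUE))
    names(cols) <- paste0("f", 1:8)
    df <- as.data.frame(cols)
    stats <- caret::nearZeroVar(df, freqCut = 19, uniqueCut = 10, saveMetrics = TRUE)
    boundary <- stats$freqRatio == 19 | stats$percentUnique == 10
    mine <- vapply(df, function(x) tabml:::nzv_stats(x)$freq_ratio >= 19 &&
                     tabml:::nzv_stats(x)$pct_unique <= 10, TRUE)
    expect_equal(unname(mine[!boundary]), stats$nzv[!boundary])
  }
})

test_that("perfectly correlated features collapse to the first column, absolutely", {
  set.seed(1)
  x <- rnorm(30)
  z <- rnorm(30)
  d <- make_ds(x = x, y = 2 * x + 3, z = z, w = -z)
  st <- collapse_correlated(d, 1)
  expect_equal(st$dataset$feature_names, c("x", "z"))
  expect_equal(st$groups, list(x = c("x", "y"), z = c("z", "w")))
})

test_that("collapse matches the transitive-closure oracle on random tables", {
  for (seed in 1:15) {
    set.seed(seed)
    n <- 40
    base <- replicate(4, rnorm(n))
    cols <- list()
    for (j in 1:8) {
      src <- sample(1:4, 1)
      cols[[paste0("f", j)]] <- if (runif(1) < 0.5) {
        runif(1, -3, 3) * base[, src] + runif(1, -1, 1)
      } else rnorm(n)
    }
    d <- do.call(make_ds, cols)
    st <- collapse_correlated(d, 1)
    expect_equal(st$groups, oracle_corr_groups(as.data.frame(cols), 1))
    # after collapsing no surviving pair reaches the threshold
    surv <- as.matrix(d$table[st$dataset$feature_names])
    if (ncol(surv) > 1) {
      cm <- abs(cor(surv))
      diag(cm) <- 0
      expect_lt(max(cm), 1 - 1e-10)
    }
  }
})

test_that("preprocess_data composes the five stages and accounts for every feature", {
  for (seed in 1:10) {
    d <- random_mixed_dataset(seed, n = 60, p = 15)
    if (is.null(d)) next
    pp <- tryCatch(suppressWarnings(preprocess_data(d)),
                   error = function(e) NULL)
    if (is.null(pp)) next
    # accounting: every original feature is surviving (some derived column
    # kept), removed, or collapsed into another representative
    survived <- pp$dataset$feature_names
    collapsed_members <- unlist(pp$correlated_groups)
    for (orig in d$feature_names) {
      derived <- if (orig %in% names(pp$feature_map)) pp$feature_map[[orig]] else orig
      accounted <- orig %in% pp$removed_features$constant ||
        any(derived %in% survived) ||
        any(derived %in% pp$removed_features$near_zero_variance) ||
        any(derived %in% collapsed_members)
      expect_true(accounted, label = sprintf("feature %s accounted (seed %d)", orig, seed))
    }
    # rows never change
    expect_equal(nrow(pp$dataset$table), nrow(d$table))
    expect_equal(pp$dataset$table[[d$outcome_name]], d$table[[d$outcome_name]])
    # correlated groups are disjoint and contain their representative
    expect_equal(anyDuplicated(collapsed_members), 0L)
    expect_true(all(mapply(function(nm, g) nm %in% g,
                           names(pp$correlated_groups), pp$correlated_groups)))
  }
})

test_that("preprocess_data equals the stage oracles applied sequentially", {
  for (seed in c(3, 17, 29)) {
    d <- random_mixed_dataset(seed, n = 80, p = 20)
    if (is.null(d)) next
    pp <- suppressWarnings(preprocess_data(d))
    # oracle composition: constants -> encode -> impute/scale -> nzv -> collapse
    s1 <- remove_constant_features(d)
    s2 <- encode_categorical(s1$dataset)
    ds <- s2$dataset
    for (nm in ds$feature_names) {
      x <- ds$table[[nm]]
      if (anyNA(x)) {
        v <- x[!is.na(x)]
        x[is.na(x)] <- if (all(v %in% c(0, 1))) 0 else median(v)
        ds$table[[nm]] <- x
      }
    }
    s3 <- normalize_continuous(ds, "center_scale")
    feats <- s3$dataset$table[s3$dataset$feature_names]
    keep <- names(feats)[!vapply(feats, oracle_nzv, TRUE, freq_cut = 19, unique_cut = 10)]
    groups <- oracle_corr_groups(feats[keep], 1)
    expect_equal(pp$dataset$feature_names, names(groups))
    expect_equal(pp$correlated_groups, groups)
    expect_equal(pp$dataset$table[pp$dataset$feature_names],
                 s3$dataset$table[names(groups)])
  }
})

test_that("preprocess_data is idempotent on its own output", {
  for (seed in 1:8) {
    d <- random_mixed_dataset(seed, n = 50, p = 12)
    if (is.null(d)) next
    pp1 <- tryCatch(suppressWarnings(preprocess_data(d)), error = function(e) NULL)
    if (is.null(pp1)) next
    pp2 <- suppressWarnings(preprocess_data(pp1$dataset))
    expect_equal(pp2$dataset$table, pp1$dataset$table, tolerance = 1e-12)
    expect_equal(pp2$dataset$feature_names, pp1$dataset$feature_names)
  }
})
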