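# Default hyperparameter grids per model type.  These are deliberately small
# "reasonable ranges"; the boundary flag in hp_performance_table() tells the
# user when the best value sits on a grid edge and the range should be
# widened.  All grids are overridable and are serialised into results for
# provenance.

SUPPORTED_MODELS <- c("glmnet_logistic", "glmnet_linear", "svm_rbf",
                      "decision_tree", "random_forest", "xgboost")

stop_unknown_model <- function(model_type) {
  stop(sprintf("unknown model type '%s'; supported types: %s",
               model_type, paste(SUPPORTED_MODELS, collapse = ", ")),
       call. = FALSE)
}

# Median heuristic for the RBF kernel width: gamma0 = 1 / median pairwise
# squared Euclidean distance, computed on (at most) the first 100 rows.
rbf_gamma_heuristic <- function(x, n_features) {
  if (is.null(x)) return(1 / max(1, n_features))
  x <- as.matrix(x)
  x <- x[seq_len(min(nrow(x), 100L)), , drop = FALSE]
  d2 <- as.numeric(stats::dist(x))^2
  med <- stats::median(d2[d2 > 0])
  if (!is.finite(med) || med <= 0) return(1 / max(1, n_features))
  1 / med
}

#' Default hyperparameter grid for a model type
#'
#' Returns the searched-by-default grid:
#' * `glmnet_logistic` / `glmnet_linear`: ridge (`alpha = 0`) with
#'   `lambda` in \{1e-4, 1e-3, 1e-2, 0.1, 1, 10\};
#' * `svm_rbf`: `cost` over the decades 1e-3..1e2 crossed with a kernel
#'   width `gamma` set by the median heuristic and one decade either side;
#' * `decision_tree`: `maxdepth` in \{1, 2, 4, 8, 16, 32\};
#' * `random_forest`: `mtry` (features per split) in
#'   \{floor(sqrt(p)/2), floor(sqrt(p)), 2 floor(sqrt(p))\}, deduplicated
#'   and at least 1;
#' * `xgboost`: `eta` in \{0.01, 0.1, 0.3\} x `max_depth` in \{2, 4, 6\} x
#'   `nrounds` = 100.
#'
#' @param model_type One of `r paste0('\x60', SUPPORTED_MODELS, '\x60', collapse = ", ")`.
#' @param n_features Number of features p (used by the random-forest and
#'   fallback svm grids).
#' @param x Optional numeric feature matrix, used by the svm median
#'   heuristic; when absent `gamma` defaults to decades around 1/p.
#' @return An object of class `ml_grid`: list with `model_type` and `params`
#'   (named list of candidate value vectors; combinations are the Cartesian
#'   product).
#' @examples
#' default_grid("random_forest", n_features = 100)$params$mtry
#' @export
default_grid <- function(model_type, n_features, x = NULL) {
  params <- switch(model_type,
    glmnet_logistic = ,
    glmnet_linear = list(alpha = 0, lambda = c(1e-4, 1e-3, 1e-2, 0.1, 1, 10)),
    svm_rbf = {
      g0 <- rbf_gamma_heuristic(x, n_features)
      list(cost = 10^(-3:2), gamma = g0 * c(0.1, 1, 10))
    },
    decision_tree = list(maxdepth = c(1, 2, 4, 8, 16, 32)),
    random_forest = {
      s <- floor(sqrt(n_features))
      list(mtry = unique(pmin(n_features, pmax(1, c(floor(s / 2), s, 2 * s)))))
    },
    xgboost = list(eta = c(0.01, 0.1, 0.3), max_depth = c(2, 4, 6), nrounds = 100),
    stop_unknown_model(model_type)
  )
  structure(list(model_type = model_type, params = params), class = "ml_grid")
}

# Grid combinations in enumeration order (first parameter varies fastest);
# ties in CV performance break toward the earlier row.
grid_combinations <- function(grid) {
  stopifnot(length(grid$params) > 0, all(lengths(grid$params) > 0))
  expand.grid(grid$params, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
}
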