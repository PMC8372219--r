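# Fitted-model handles.  Every backend (glmnet, e1071, rpart, randomForest,
# xgboost) is wrapped in an `ml_model` exposing exactly two contracts used by
# all downstream code:
#   * score_model(model, x): class-probability matrix (classification, one
#     column per outcome level) or numeric predictions (regression);
#   * predict(model, x): point predictions (binary uses cutoff 0.5 on the
#     positive-class score).

new_ml_model <- function(fit, model_type, outcome_kind, levels = NULL,
                         positive = NULL, feature_names, params = list(),
                         score_fun = NULL) {
  structure(
    list(fit = fit, model_type = model_type, outcome_kind = outcome_kind,
         levels = levels, positive = positive, feature_names = feature_names,
         params = params, score_fun = score_fun),
    class = "ml_model"
  )
}

is_classification <- function(outcome_kind) outcome_kind %in% c("binary", "multiclass")

check_model_outcome <- function(model_type, outcome_kind) {
  if (model_type == "glmnet_logistic" && !is_classification(outcome_kind)) {
    stop("glmnet_logistic requires a binary or multiclass outcome", call. = FALSE)
  }
  if (model_type == "glmnet_linear" && outcome_kind != "continuous") {
    stop("glmnet_linear requires a continuous outcome", call. = FALSE)
  }
}

# rpart needs syntactic names; rename features to .f1...fp internally.
rpart_frame <- function(x) {
  df <- as.data.frame(x)
  colnames(df) <- paste0(".f", seq_len(ncol(df)))
  df
}

# Fit one model with one hyperparameter combination.  `seed` makes the
# stochastic learners (random forest, svm probability calibration, xgboost)
# deterministic.
fit_model <- function(x, y, model_type, params, outcome_kind, seed = 0L,
                      positive = NULL) {
  check_model_outcome(model_type, outcome_kind)
  x <- as.matrix(x)
  classif <- is_classification(outcome_kind)
  levels <- NULL
  if (classif) {
    levels <- sort(unique(as.character(y)))
    y <- factor(as.character(y), levels = levels)
    if (is.null(positive)) positive <- if (length(levels) >= 2) levels[2] else levels[1]
  } else {
    y <- as.numeric(y)
  }

  fit <- with_seed(seed, switch(model_type,
    glmnet_logistic = ,
    glmnet_linear = {
      lam <- params$lambda
      family <- if (!classif) "gaussian"
                else if (length(levels) == 2) "binomial" else "multinomial"
      path <- sort(unique(c(lam, lam * c(10, 100, 1000))), decreasing = TRUE)
      glmnet::glmnet(x, y, family = family, alpha = params$alpha, lambda = path)
    },
    svm_rbf = {
      e1071::svm(x = x, y = y, kernel = "radial", cost = params$cost,
                 gamma = params$gamma, probability = classif, scale = FALSE)
    },
    decision_tree = {
      df <- rpart_frame(x)
      df$.outcome <- y
      rpart::rpart(.outcome ~ ., data = df,
                   method = if (classif) "class" else "anova",
                   control = rpart::rpart.control(
                     maxdepth = min(params$maxdepth, 30), cp = 0.001, xval = 0))
    },
    random_forest = {
      randomForest::randomForest(x = x, y = y,
                                 mtry = min(params$mtry, ncol(x)), ntree = 500)
    },
    xgboost = {
      label <- if (!classif) y
               else if (length(levels) == 2) as.numeric(y == levels[2])
               else as.numeric(y) - 1
      objective <- if (!classif) "reg:squarederror"
                   else if (length(levels) == 2) "binary:logistic" else "multi:softprob"
      xp <- list(eta = params$eta, max_depth = params$max_depth,
                 objective = objective, nthread = 1)
      if (classif && length(levels) > 2) xp$num_class <- length(levels)
      xgboost::xgb.train(params = xp,
                         data = xgboost::xgb.DMatrix(x, label = label),
                         nrounds = params$nrounds, verbose = 0)
    },
    stop_unknown_model(model_type)
  ))

  new_ml_model(fit, model_type, outcome_kind, levels = levels,
               positive = positive, feature_names = colnames(x), params = params)
}

#' Score a fitted model on new data
#'
#' For classification returns a matrix of probability-like class scores with
#' one named column per outcome level; for regression returns a numeric
#' vector of predictions. This is the only scoring contract downstream
#' modules (evaluation, permutation importance) rely on.
#'
#' @param model An `ml_model` handle.
#' @param x Numeric feature matrix with the training columns.
#' @return Probability matrix or numeric vector.
#' @export
score_model <- function(model, x) {
  x <- as.matrix(x)
  if (!is.null(model$score_fun)) return(model$score_fun(x))
  classif <- is_classification(model$outcome_kind)
  L <- model$levels
  out <- switch(model$model_type,
    glmnet_logistic = {
      lam <- model$params$lambda
      if (length(L) == 2) {
        p <- as.numeric(stats::predict(model$fit, newx = x, s = lam,
                                       type = "response"))
        cbind(1 - p, p)
      } else {
        pr <- stats::predict(model$fit, newx = x, s = lam, type = "response")
        matrix(pr, nrow = nrow(x), ncol = length(L),
               dimnames = list(NULL, dimnames(pr)[[2]]))[, L, drop = FALSE]
      }
    },
    glmnet_linear = as.numeric(stats::predict(model$fit, newx = x,
                                              s = model$params$lambda)),
    svm_rbf = {
      if (classif) {
        pr <- attr(stats::predict(model$fit, x, probability = TRUE),
                   "probabilities")
        pr[, L, drop = FALSE]
      } else {
        as.numeric(stats::predict(model$fit, x))
      }
    },
    decision_tree = {
      df <- rpart_frame(x)
      if (classif) {
        pr <- stats::predict(model$fit, df, type = "prob")
        pr[, L, drop = FALSE]
      } else {
        as.numeric(stats::predict(model$fit, df))
      }
    },
    random_forest = {
      if (classif) {
        pr <- stats::predict(model$fit, x, type = "prob")
        pr[, L, drop = FALSE]
      } else {
        as.numeric(stats::predict(model$fit, x))
      }
    },
    xgboost = {
      p <- stats::predict(model$fit, xgboost::xgb.DMatrix(x))
      if (!classif) as.numeric(p)
      else if (length(L) == 2) cbind(1 - as.numeric(p), as.numeric(p))
      else if (is.matrix(p)) p
      else matrix(p, nrow = nrow(x), ncol = length(L), byrow = TRUE)
    },
    stop_unknown_model(model$model_type)
  )
  if (classif && is.matrix(out)) colnames(out) <- L
  out
}

#' Predict from a fitted model handle
#'
#' Point predictions: for binary outcomes the positive class is predicted
#' when its score is at least 0.5; multiclass predicts the highest-scoring
#' class; regression returns numeric predictions.
#'
#' @param object An `ml_model`.
#' @param newdata Numeric feature matrix or data.frame.
#' @param ... Unused.
#' @return Character vector of class labels, or numeric predictions.
#' @export
predict.ml_model <- function(object, newdata, ...) {
  sc <- score_model(object, newdata)
  if (!is_classification(object$outcome_kind)) return(sc)
  L <- object$levels
  if (length(L) == 2) {
    pos <- object$positive
    ifelse(sc[, pos] >= 0.5, pos, setdiff(L, pos))
  } else {
    L[max.col(sc, ties.method = "first")]
  }
}

#' @export
print.ml_model <- function(x, ...) {
  cat(sprintf("<ml_model> %s (%s outcome, %d features)\n",
              x$model_type, x$outcome_kind, length(x$feature_names)))
  if (length(x$params)) {
    cat("  params:", paste(names(x$params), unlist(x$params),
                           sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

# Test / extension hook: a handle backed by an arbitrary scoring function.
custom_model <- function(score_fun, outcome_kind, levels = NULL,
                         positive = NULL, feature_names = NULL) {
  new_ml_model(NULL, "custom", outcome_kind, levels = levels,
               positive = positive, feature_names = feature_names,
               score_fun = score_fun)
}
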