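#' Classifier specification
#'
#' Declares one of the three learners used by the benchmarking harness and
#' its hyperparameter tuning grid. Tuning happens by nested (inner)
#' stratified cross-validation inside each outer training fold; a grid with a
#' single row skips the inner loop.
#'
#' Default grids (deliberately small; the learners are robust to these
#' choices and the grids are fully configurable):
#' * `random_forest` (ranger): 500 trees; `mtry` sqrt(n) or 0.1 n;
#'   `min.node.size` 1 or 5.
#' * `gradient_boosting` (xgboost): 100 or 300 rounds; learning rate 0.05 or
#'   0.1; depth 2 or 3.
#' * `lasso_logistic` (glmnet): L1-penalized logistic regression; a 10-value
#'   lambda path computed on the training data, inner-CV selected. Features
#'   are standardized internally from training rows only.
#'
#' @param kind `"random_forest"`, `"gradient_boosting"` or
#'   `"lasso_logistic"`.
#' @param tuning_grid Data frame of candidate hyperparameter rows; see
#'   [default_tuning_grid()]. Ignored for `lasso_logistic`, whose grid is the
#'   data-driven lambda path.
#' @param inner_folds Folds of the inner tuning CV (default 3).
#' @return A `classifier_spec`.
#' @export
classifier_spec <- function(kind = c("random_forest", "gradient_boosting", "lasso_logistic"),
                            tuning_grid = default_tuning_grid(kind),
                            inner_folds = 3L) {
  kind <- match.arg(kind)
  inner_folds <- as.integer(inner_folds)
  if (inner_folds < 2L) stop("inner_folds must be >= 2")
  if (kind != "lasso_logistic" && (!is.data.frame(tuning_grid) || nrow(tuning_grid) < 1L)) {
    stop("tuning_grid must be a non-empty data frame")
  }
  structure(list(kind = kind, tuning_grid = tuning_grid, inner_folds = inner_folds),
            class = "classifier_spec")
}

#' @rdname classifier_spec
#' @param n_lambda Length of the lasso lambda path.
#' @export
default_tuning_grid <- function(kind, n_lambda = 10L) {
  kind <- match.arg(kind, c("random_forest", "gradient_boosting", "lasso_logistic"))
  switch(kind,
    random_forest = expand.grid(num.trees = 500L,
                                mtry_rule = c("sqrt", "frac0.1"),
                                min.node.size = c(1L, 5L),
                                stringsAsFactors = FALSE),
    gradient_boosting = expand.grid(nrounds = c(100L, 300L),
                                    eta = c(0.05, 0.1),
                                    max_depth = c(2L, 3L),
                                    stringsAsFactors = FALSE),
    lasso_logistic = data.frame(n_lambda = as.integer(n_lambda)))
}

resolve_mtry <- function(rule, n) {
  v <- switch(as.character(rule),
              sqrt = floor(sqrt(n)),
              frac0.1 = floor(0.1 * n),
              as.integer(rule))
  max(1L, min(n, as.integer(v)))
}

# Fit one learner with one hyperparameter row; returns a list with a
# `predict_scores(newx)` closure and an `importance()` closure returning a
# named vector over all training features.
fit_classifier <- function(kind, x, y, params, seed) {
  fn <- colnames(x)
  if (kind == "random_forest") {
    fit <- ranger::ranger(x = x, y = factor(y, levels = c(0, 1)),
                          num.trees = params$num.trees,
                          mtry = resolve_mtry(params$mtry_rule, ncol(x)),
                          min.node.size = params$min.node.size,
                          probability = TRUE, importance = "impurity",
                          num.threads = 1L, seed = seed, verbose = FALSE)
    list(predict_scores = function(newx) {
           stats::predict(fit, data = newx, num.threads = 1L,
                          verbose = FALSE)$predictions[, "1"]
         },
         importance = function() fit$variable.importance[fn])
  } else if (kind == "gradient_boosting") {
    dtr <- xgboost::xgb.DMatrix(x, label = y)
    fit <- with_seed(seed,
      xgboost::xgb.train(params = list(objective = "binary:logistic",
                                       eta = params$eta,
                                       max_depth = params$max_depth,
                                       nthread = 1L),
                         data = dtr, nrounds = params$nrounds, verbose = 0))
    list(predict_scores = function(newx) {
           stats::predict(fit, xgboost::xgb.DMatrix(newx))
         },
         importance = function() {
           imp <- xgboost::xgb.importance(model = fit)
           out <- stats::setNames(rep(0, length(fn)), fn)
           out[imp$Feature] <- imp$Gain
           out
         })
  } else { # lasso_logistic
    # fit the full path and evaluate at the tuned lambda: glmnet's warm-started
    # path is more stable than a single-lambda fit
    fit <- glmnet::glmnet(x, y, family = "binomial", alpha = 1,
                          nlambda = 30L, standardize = TRUE)
    lam <- params$lambda
    list(predict_scores = function(newx) {
           as.numeric(stats::predict(fit, newx, s = lam, type = "response"))
         },
         importance = function() {
           cf <- as.matrix(stats::coef(fit, s = lam))[-1L, 1L]
           stats::setNames(abs(cf), fn)
         })
  }
}

# Candidate hyperparameter rows for tuning on a given training matrix; for
# the lasso this is where the data-driven lambda path is computed.
candidate_grid <- function(clf, x, y) {
  if (clf$kind != "lasso_logistic") return(clf$tuning_grid)
  n_lambda <- if (!is.null(clf$tuning_grid$n_lambda)) clf$tuning_grid$n_lambda[1L] else 10L
  path <- glmnet::glmnet(x, y, family = "binomial", alpha = 1,
                         nlambda = n_lambda, standardize = TRUE)$lambda
  data.frame(lambda = path)
}

# Inner-CV tuning + final fit on (x, y). Uses the current RNG stream for fold
# assignment and sub-seeds; returns list(model, params).
tune_and_fit <- function(x, y, clf, seed) {
  with_seed(seed, {
    grid <- candidate_grid(clf, x, y)
    best <- 1L
    if (nrow(grid) > 1L) {
      folds <- stratified_folds(y, clf$inner_folds)
      mean_auc <- numeric(nrow(grid))
      fold_seeds <- replicate(clf$inner_folds, draw_seed())
      for (g in seq_len(nrow(grid))) {
        aucs <- vapply(seq_len(clf$inner_folds), function(f) {
          tr <- folds != f
          if (length(unique(y[!tr])) < 2L) return(NA_real_)
          mod <- fit_classifier(clf$kind, x[tr, , drop = FALSE], y[tr],
                                grid[g, , drop = FALSE], seed = fold_seeds[f])
          auc(mod$predict_scores(x[!tr, , drop = FALSE]), y[!tr])
        }, numeric(1))
        mean_auc[g] <- mean(aucs, na.rm = TRUE)
      }
      best <- which.max(mean_auc)
    }
    params <- grid[best, , drop = FALSE]
    list(model = fit_classifier(clf$kind, x, y, params, seed = draw_seed()),
         params = params)
  })
}
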