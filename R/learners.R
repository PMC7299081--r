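# Learner registry: each learner is a list(fit, predict) pair operating on
# a numeric matrix of selected features. Hyperparameters are fixed, modest
# defaults; there is no per-fold tuning.

learner_lm <- list(
  fit = function(x, y, seed = 0) {
    df <- data.frame(x, check.names = FALSE)
    df$.y <- y
    stats::lm(.y ~ ., data = df)
  },
  predict = function(fit, x) {
    unname(stats::predict(fit, newdata = data.frame(x, check.names = FALSE)))
  }
)

learner_rf <- list(
  fit = function(x, y, seed = 0) {
    ranger::ranger(
      x = x, y = y, num.trees = 300, seed = seed, num.threads = 1
    )
  },
  predict = function(fit, x) {
    stats::predict(fit, data = x, num.threads = 1)$predictions
  }
)

learner_svm <- list(
  fit = function(x, y, seed = 0) e1071::svm(x, y, kernel = "radial"),
  predict = function(fit, x) unname(stats::predict(fit, x))
)

learner_xgb <- list(
  fit = function(x, y, seed = 0) {
    xgboost::xgb.train(
      params = list(
        eta = 0.1, max_depth = 3, subsample = 0.8, nthread = 1,
        seed = seed, objective = "reg:squarederror"
      ),
      data = xgboost::xgb.DMatrix(x, label = y), nrounds = 80, verbose = 0
    )
  },
  predict = function(fit, x) {
    stats::predict(fit, xgboost::xgb.DMatrix(x))
  }
)

# Logistic regression enters the score regression by dichotomizing the
# training outcome at its 25th percentile and rescaling the predicted
# probability of scoring at-or-above that cutoff back to the training score
# range. This is an interpretation choice: a classifier can only contribute
# to a continuous prediction through a rescaled probability.
learner_logistic <- list(
  fit = function(x, y, seed = 0) {
    cut <- percentile_nearest_rank(y, 25)
    flag <- as.integer(y >= cut)
    df <- data.frame(x, check.names = FALSE)
    df$.y <- flag
    fit <- suppressWarnings(
      stats::glm(.y ~ ., data = df, family = stats::binomial())
    )
    list(glm = fit, y_min = min(y), y_max = max(y))
  },
  predict = function(fit, x) {
    p <- suppressWarnings(stats::predict(
      fit$glm,
      newdata = data.frame(x, check.names = FALSE), type = "response"
    ))
    unname(fit$y_min + p * (fit$y_max - fit$y_min))
  }
)

#' The registered prediction functions
#'
#' Five learners: linear regression, random forest, support vector machine
#' (radial kernel), extreme gradient boosting, and logistic regression on
#' the outcome dichotomized at the training 25th percentile (contributing
#' its probability rescaled to the score range).
#'
#' @param which Optional character subset of learner names.
#' @return Named list of `list(fit, predict)` pairs.
#' @export
deep_learners <- function(which = NULL) {
  all <- list(
    linear_regression = learner_lm,
    random_forest = learner_rf,
    svm = learner_svm,
    xgboost = learner_xgb,
    logistic_regression = learner_logistic
  )
  if (is.null(which)) all else all[which]
}
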