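#' Cross-validation and ensembling configuration
#'
#' @param train_fraction Fraction of children assigned to training
#'   (default 0.70).
#' @param k_folds Folds per cross-validation run (default 10).
#' @param repeats Repeats of the k-fold loop, averaged for stability
#'   (default 10).
#' @param seed Integer seed controlling the split and fold assignment.
#' @param selector_cap Maximum features a selector may return (default 15).
#' @param n_top_models Base models kept for ensembling (default 5).
#' @param stack_weights Weights of the linear-regression, random-forest and
#'   gradient-boosting stacking functions; must sum to 1 (default
#'   0.25/0.25/0.50).
#' @param selectors,learners Optional name subsets of [deep_selectors()] /
#'   [deep_learners()].
#' @return A validated `cv_config` list.
#' @export
cv_config <- function(train_fraction = 0.70, k_folds = 10, repeats = 10,
                      seed = 1, selector_cap = 15, n_top_models = 5,
                      stack_weights = c(
                        linear_regression = 0.25, random_forest = 0.25,
                        xgboost = 0.50
                      ),
                      selectors = NULL, learners = NULL) {
  stopifnot(
    "train_fraction must be in (0, 1)" =
      train_fraction > 0 && train_fraction < 1,
    "k_folds must be at least 2" = k_folds >= 2,
    "repeats must be at least 1" = repeats >= 1,
    "selector_cap must be at least 1" = selector_cap >= 1,
    "stack_weights must have 3 elements" = length(stack_weights) == 3,
    "stack_weights must sum to 1" =
      abs(sum(stack_weights) - 1) < 1e-8
  )
  structure(
    list(
      train_fraction = train_fraction, k_folds = k_folds, repeats = repeats,
      seed = seed, selector_cap = selector_cap, n_top_models = n_top_models,
      stack_weights = stack_weights, selectors = selectors,
      learners = learners
    ),
    class = "cv_config"
  )
}

#' Split a cohort into training and test children
#'
#' Random split by the configured seed; the training share is the rounded
#' `train_fraction` of the cohort, so proportions are within one child of
#' the target (200 children give 140/60). The returned test ids must stay
#' untouched until final evaluation.
#'
#' @param cohort A `deep_cohort` (or any list with a `children` tibble).
#' @param cv A [cv_config()].
#' @return List with `train_ids` and `test_ids`.
#' @export
split_train_test <- function(cohort, cv = cv_config()) {
  ids <- cohort$children$child_id
  n <- length(ids)
  if (n < 10) stop("refusing to split fewer than 10 children", call. = FALSE)
  set.seed(cv$seed)
  n_train <- round(cv$train_fraction * n)
  train <- sort(sample(ids, n_train))
  list(train_ids = train, test_ids = sort(setdiff(ids, train)))
}

#' Repeated k-fold cross-validation over the selector x learner grid
#'
#' For each repeat, children are assigned to `k_folds` folds; within each
#' fold every selector picks at most `selector_cap` features on the
#' training folds, every learner fits on them and predicts the holdout
#' fold. Out-of-fold predictions are averaged over repeats, and each
#' (selector, learner) combination is scored by the Pearson correlation of
#' its averaged out-of-fold predictions with the outcome. A learner failing
#' on any fold flags the combination as failed.
#'
#' @param fm_train A `deep_features` restricted to the training children
#'   (see [fm_filter()] via [assemble_feature_set()] and the split).
#' @param y_train Outcome aligned to `fm_train` rows.
#' @param cv A [cv_config()].
#' @return Tibble of model results: `selector`, `learner`, `model`,
#'   `holdout_r`, `n_features`, `failed`, and the out-of-fold prediction
#'   vector in `oof` (list-column).
#' @export
run_repeated_cv <- function(fm_train, y_train, cv = cv_config()) {
  x <- fm_matrix(fm_train)
  n <- nrow(x)
  selectors <- deep_selectors(cv$selectors)
  learners <- deep_learners(cv$learners)
  grid <- tidyr::expand_grid(
    selector = names(selectors), learner = names(learners)
  )
  n_models <- nrow(grid)
  pred_sum <- matrix(0, n, n_models)
  pred_cnt <- matrix(0L, n, n_models)
  failed <- logical(n_models)
  feat_count <- numeric(n_models)
  feat_folds <- 0L

  for (r in seq_len(cv$repeats)) {
    set.seed(cv$seed + 131 * r)
    folds <- sample(rep_len(seq_len(cv$k_folds), n))
    for (f in seq_len(cv$k_folds)) {
      ho <- which(folds == f)
      tr <- which(folds != f)
      sel_feats <- purrr::map(seq_along(selectors), function(s) {
        tryCatch(
          selectors[[s]](x[tr, , drop = FALSE], y_train[tr],
            cap = cv$selector_cap, seed = cv$seed + 31 * r + f
          ),
          error = function(e) NULL
        )
      })
      feat_folds <- feat_folds + 1L
      for (m in seq_len(n_models)) {
        s <- match(grid$selector[m], names(selectors))
        feats <- sel_feats[[s]]
        if (is.null(feats) || length(feats) == 0) {
          failed[m] <- TRUE
          next
        }
        feat_count[m] <- feat_count[m] + length(feats)
        lrn <- learners[[grid$learner[m]]]
        p <- tryCatch(
          {
            fit <- lrn$fit(x[tr, feats, drop = FALSE], y_train[tr],
              seed = cv$seed + 17 * r + f
            )
            lrn$predict(fit, x[ho, feats, drop = FALSE])
          },
          error = function(e) NULL
        )
        if (is.null(p) || length(p) != length(ho) || anyNA(p)) {
          failed[m] <- TRUE
        } else {
          pred_sum[ho, m] <- pred_sum[ho, m] + p
          pred_cnt[ho, m] <- pred_cnt[ho, m] + 1L
        }
      }
    }
  }
  oof <- pred_sum / pmax(pred_cnt, 1)
  oof[pred_cnt == 0] <- NA_real_
  grid$model <- paste(grid$selector, grid$learner, sep = "_x_")
  grid$holdout_r <- vapply(seq_len(n_models), function(m) {
    if (failed[m]) return(NA_real_)
    suppressWarnings(stats::cor(oof[, m], y_train))
  }, numeric(1))
  grid$n_features <- feat_count / feat_folds
  grid$failed <- failed | is.na(grid$holdout_r)
  grid$oof <- purrr::map(seq_len(n_models), function(m) oof[, m])
  grid
}

#' Rank model results and keep the top performers
#'
#' Descending holdout correlation; ties break by smaller mean selected
#' feature count, then lexicographic model name.
#'
#' @param results Output of [run_repeated_cv()].
#' @param cv A [cv_config()]; `n_top_models` are returned.
#' @return The top rows of `results`.
#' @export
rank_and_select <- function(results, cv = cv_config()) {
  viable <- dplyr::filter(results, !.data$failed)
  if (nrow(viable) < cv$n_top_models) {
    stop(
      "only ", nrow(viable), " viable models; need ", cv$n_top_models,
      " - enlarge the selector/learner grid",
      call. = FALSE
    )
  }
  ranked <- dplyr::arrange(
    viable, dplyr::desc(.data$holdout_r), .data$n_features, .data$model
  )
  ranked[seq_len(cv$n_top_models), ]
}

#' Build the stacked ensemble from the top models
#'
#' Each top (selector, learner) pair is refit on the full training set,
#' with its feature list re-selected on the full training data. Three
#' stacking functions (linear regression, random forest, gradient
#' boosting) are then fitted on the out-of-fold predictions of the top
#' models against the training outcome. If the out-of-fold design is
#' degenerate (a constant column), the linear stacker falls back to the
#' training-mean predictor with a warning.
#'
#' @param top Output of [rank_and_select()].
#' @param fm_train Training-rows `deep_features`.
#' @param y_train Training outcome.
#' @param cv A [cv_config()].
#' @param support Score support used to clamp final predictions.
#' @return A `deep_ensemble` object.
#' @export
build_ensemble <- function(top, fm_train, y_train, cv = cv_config(),
                           support = c(57, 88)) {
  x <- fm_matrix(fm_train)
  selectors <- deep_selectors(cv$selectors)
  learners <- deep_learners(cv$learners)
  base <- purrr::map(seq_len(nrow(top)), function(i) {
    feats <- selectors[[top$selector[i]]](
      x, y_train, cap = cv$selector_cap, seed = cv$seed
    )
    lrn <- learners[[top$learner[i]]]
    fit <- lrn$fit(x[, feats, drop = FALSE], y_train, seed = cv$seed)
    list(
      selector = top$selector[i], learner = top$learner[i],
      model = top$model[i], features = feats, fit = fit,
      predict = lrn$predict, holdout_r = top$holdout_r[i]
    )
  })
  z <- do.call(cbind, top$oof)
  colnames(z) <- paste0("base", seq_len(ncol(z)))
  degenerate <- apply(z, 2, stats::sd) == 0
  if (any(degenerate)) {
    warning("constant out-of-fold predictions in the stacker design; ",
      "linear stacker falls back to the mean predictor")
  }
  stack_lm <- if (any(degenerate)) {
    mu <- mean(y_train)
    list(predict = function(z_new) rep(mu, nrow(z_new)))
  } else {
    df <- data.frame(z)
    df$.y <- y_train
    fit <- stats::lm(.y ~ ., data = df)
    list(predict = function(z_new) {
      colnames(z_new) <- colnames(z)
      unname(stats::predict(fit, newdata = data.frame(z_new)))
    })
  }
  rf_fit <- ranger::ranger(
    x = z, y = y_train, num.trees = 300, seed = cv$seed, num.threads = 1
  )
  stack_rf <- list(predict = function(z_new) {
    stats::predict(rf_fit, data = z_new, num.threads = 1)$predictions
  })
  xgb_fit <- xgboost::xgb.train(
    params = list(
      eta = 0.1, max_depth = 2, nthread = 1, seed = cv$seed,
      objective = "reg:squarederror"
    ),
    data = xgboost::xgb.DMatrix(z, label = y_train), nrounds = 80, verbose = 0
  )
  stack_xgb <- list(predict = function(z_new) {
    stats::predict(xgb_fit, xgboost::xgb.DMatrix(z_new))
  })
  # fold-held-out stacked scores for the training children themselves:
  # refitting memorizing learners on the full training set makes in-sample
  # train metrics incomparable with test metrics, so training children are
  # evaluated on predictions from stackers that never saw their row
  train_oof <- rep(NA_real_, nrow(z))
  set.seed(cv$seed + 777L)
  oof_folds <- sample(rep_len(seq_len(5), nrow(z)))
  for (f in seq_len(5)) {
    ho <- which(oof_folds == f)
    tr <- which(oof_folds != f)
    p_lm <- tryCatch(
      {
        df <- data.frame(z[tr, , drop = FALSE])
        df$.y <- y_train[tr]
        fit <- stats::lm(.y ~ ., data = df)
        unname(stats::predict(fit, newdata = data.frame(z[ho, , drop = FALSE])))
      },
      error = function(e) rep(mean(y_train[tr]), length(ho))
    )
    rf_f <- ranger::ranger(
      x = z[tr, , drop = FALSE], y = y_train[tr], num.trees = 300,
      seed = cv$seed + f, num.threads = 1
    )
    p_rf <- stats::predict(rf_f, data = z[ho, , drop = FALSE],
      num.threads = 1)$predictions
    xgb_f <- xgboost::xgb.train(
      params = list(
        eta = 0.1, max_depth = 2, nthread = 1, seed = cv$seed + f,
        objective = "reg:squarederror"
      ),
      data = xgboost::xgb.DMatrix(z[tr, , drop = FALSE],
        label = y_train[tr]), nrounds = 80, verbose = 0
    )
    p_xgb <- stats::predict(xgb_f, xgboost::xgb.DMatrix(z[ho, , drop = FALSE]))
    train_oof[ho] <- cbind(p_lm, p_rf, p_xgb) %*% cv$stack_weights
  }
  train_oof <- clamp(train_oof, min(support), max(support))
  structure(
    list(
      base_models = base,
      stackers = list(
        linear_regression = stack_lm, random_forest = stack_rf,
        xgboost = stack_xgb
      ),
      weights = cv$stack_weights,
      support = support,
      train_ids = fm_train$data$child_id,
      train_oof = tibble::tibble(
        child_id = fm_train$data$child_id, deep_score = train_oof
      ),
      cv = cv
    ),
    class = "deep_ensemble"
  )
}

#' @export
print.deep_ensemble <- function(x, ...) {
  cat("<deep_ensemble> ", length(x$base_models), " base models, ",
    length(x$stackers), " stackers, weights ",
    paste(x$weights, collapse = "/"), "\n",
    sep = ""
  )
  for (b in x$base_models) {
    cat(sprintf(
      "  %-40s %2d features  CV r = %.3f\n", b$model, length(b$features),
      b$holdout_r
    ))
  }
  invisible(x)
}

# specific game codes a feature depends on (empty for across-game features)
contributing_games <- function(ensemble, fm) {
  feats <- unique(unlist(purrr::map(ensemble$base_models, "features")))
  games <- fm$meta$games[match(feats, fm$meta$name)]
  unique(unlist(strsplit(games[!is.na(games) & nzchar(games)], ",")))
}

#' Predict DEEP scores with a fitted ensemble
#'
#' The final score is the weighted average of the three stacked
#' predictions (default 0.25 linear + 0.25 random forest + 0.50 gradient
#' boosting), clamped to the score support. Children who did not attempt
#' an entire game that contributes any base-model feature cannot be
#' meaningfully imputed and are excluded rather than predicted; their ids
#' are attached as `attr(, "excluded")`.
#'
#' @param ensemble A `deep_ensemble`.
#' @param fm A `deep_features` covering the children to predict (its
#'   columns must include every base-model feature).
#' @return Tibble `child_id`, `deep_score` for predictable children.
#' @export
predict_deep_scores <- function(ensemble, fm) {
  x <- fm_matrix(fm)
  needed <- unique(unlist(purrr::map(ensemble$base_models, "features")))
  missing_cols <- setdiff(needed, colnames(x))
  if (length(missing_cols) > 0) {
    stop("feature matrix lacks base-model features: ",
      paste(utils::head(missing_cols, 5), collapse = ", "),
      call. = FALSE
    )
  }
  games <- contributing_games(ensemble, fm)
  lacking <- rowSums(!fm$games_attempted[, games, drop = FALSE]) > 0
  if (all(lacking)) {
    stop("every child lacks a contributing game; nothing to predict",
      call. = FALSE
    )
  }
  keep <- which(!lacking)
  z <- vapply(
    ensemble$base_models,
    function(b) b$predict(b$fit, x[keep, b$features, drop = FALSE]),
    numeric(length(keep))
  )
  z <- matrix(z, nrow = length(keep))
  colnames(z) <- paste0("base", seq_len(ncol(z)))
  stacked <- vapply(
    ensemble$stackers, function(s) s$predict(z), numeric(length(keep))
  )
  stacked <- matrix(stacked, nrow = length(keep))
  deep <- as.vector(stacked %*% ensemble$weights)
  deep <- clamp(deep, min(ensemble$support), max(ensemble$support))
  out <- tibble::tibble(
    child_id = fm$data$child_id[keep], deep_score = deep
  )
  attr(out, "excluded") <- fm$data$child_id[lacking]
  out
}
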