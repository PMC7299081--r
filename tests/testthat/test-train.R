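test_that("the train/test split follows the 70/30 rounding rule", {
  fake <- list(children = tibble::tibble(child_id = sprintf("c%03d", 1:200)))
  sp <- split_train_test(fake, cv_config(seed = 4))
  expect_length(sp$train_ids, 140)
  expect_length(sp$test_ids, 60)
  expect_length(intersect(sp$train_ids, sp$test_ids), 0)

  fake10 <- list(children = tibble::tibble(child_id = sprintf("c%03d", 1:10)))
  sp10 <- split_train_test(fake10, cv_config(seed = 4))
  expect_length(sp10$train_ids, 7)
  expect_length(sp10$test_ids, 3)

  sp2 <- split_train_test(fake, cv_config(seed = 4))
  expect_identical(sp, sp2)
  fake9 <- list(children = tibble::tibble(child_id = sprintf("c%03d", 1:9)))
  expect_error(split_train_test(fake9, cv_config()), "fewer than 10")
})

test_that("every selector respects the cap and returns real columns", {
  set.seed(5)
  x <- matrix(stats::rnorm(100 * 60), 100, 60)
  colnames(x) <- sprintf("f%02d", 1:60)
  y <- x[, 1] - x[, 2] + stats::rnorm(100, sd = 0.5)
  for (sel in deep_selectors()) {
    feats <- sel(x, y, cap = 15, seed = 1)
    expect_lte(length(feats), 15)
    expect_gte(length(feats), 1)
    expect_true(all(feats %in% colnames(x)))
  }
  # the strongly informative columns surface in the correlation selector
  expect_true(all(c("f01", "f02") %in% deep_selectors()$correlation(x, y, 15)))
})

test_that("a leaked outcome column drives holdout correlation to one", {
  set.seed(6)
  n <- 60
  y <- stats::rnorm(n, 70, 6)
  x <- cbind(leak = y, matrix(stats::rnorm(n * 5), n, 5))
  colnames(x) <- c("leak", paste0("noise", 1:5))
  fm <- toy_fm(x)
  cv <- cv_config(
    k_folds = 2, repeats = 1, seed = 7,
    selectors = "correlation", learners = "linear_regression"
  )
  res <- run_repeated_cv(fm, y, cv)
  expect_equal(nrow(res), 1)
  expect_gt(res$holdout_r, 0.99)
})

test_that("the full grid yields one result per selector-learner pair", {
  run <- mini_run()
  expect_equal(nrow(run$cv_results), 35)
  expect_equal(
    sort(unique(run$cv_results$selector)), sort(names(deep_selectors()))
  )
  expect_equal(
    sort(unique(run$cv_results$learner)), sort(names(deep_learners()))
  )
  # out-of-fold predictions cover every training child
  oof <- run$cv_results$oof[[which.max(run$cv_results$holdout_r)]]
  expect_false(anyNA(oof))
  expect_length(oof, length(run$split$train_ids))
})

test_that("repeated CV is reproducible under a fixed seed", {
  set.seed(8)
  n <- 40
  y <- stats::rnorm(n)
  x <- matrix(stats::rnorm(n * 10), n, 10)
  colnames(x) <- paste0("f", 1:10)
  cv <- cv_config(
    k_folds = 4, repeats = 2, seed = 11,
    selectors = c("correlation", "lasso"),
    learners = c("linear_regression", "xgboost")
  )
  r1 <- run_repeated_cv(toy_fm(x), y, cv)
  r2 <- run_repeated_cv(toy_fm(x), y, cv)
  expect_equal(r1$holdout_r, r2$holdout_r)
  expect_equal(r1$oof, r2$oof)
})

test_that("ranking is by correlation with the documented tie-breaks", {
  results <- tibble::tibble(
    selector = "s", learner = "l",
    model = c("m1", "m2", "m3", "m4", "m5", "m6", "m7"),
    holdout_r = c(0.7, 0.6, 0.5, 0.4, 0.3, 0.3, 0.1),
    n_features = c(10, 10, 10, 10, 12, 8, 10),
    failed = FALSE,
    oof = replicate(7, stats::rnorm(5), simplify = FALSE)
  )
  top <- rank_and_select(results, cv_config())
  expect_equal(top$model, c("m1", "m2", "m3", "m4", "m6"))

  # a tie on both correlation and feature count falls back to the name
  results$n_features <- 10
  top2 <- rank_and_select(results, cv_config())
  expect_equal(top2$model[5], "m5")

  results$failed <- TRUE
  expect_error(rank_and_select(results, cv_config()), "viable")
})

test_that("the perfect-information limit reproduces the outcome", {
  set.seed(9)
  n <- 80
  y <- round(stats::runif(n, 60, 85))
  x <- cbind(signal = y, matrix(stats::rnorm(n * 4), n, 4))
  colnames(x) <- c("signal", paste0("noise", 1:4))
  fm <- toy_fm(x)
  cv <- cv_config(seed = 10, selectors = "correlation",
                  learners = "linear_regression")
  top <- tibble::tibble(
    selector = "correlation", learner = "linear_regression",
    model = paste0("m", 1:5), holdout_r = 1, n_features = 1,
    failed = FALSE, oof = replicate(5, y, simplify = FALSE)
  )
  ens <- suppressWarnings(
    build_ensemble(top, fm, y, cv, support = c(0, 100))
  )
  expect_length(ens$base_models, 5)
  pred <- suppressWarnings(predict_deep_scores(ens, fm))
  expect_gt(stats::cor(pred$deep_score, y), 0.98)
  expect_lt(mean(abs(pred$deep_score - y)), 2)
})

test_that("stacking averages independent predictors into a better one", {
  set.seed(12)
  n <- 120
  y <- stats::rnorm(n, 70, 6)
  noisy <- replicate(5, y + stats::rnorm(n, sd = 4), simplify = FALSE)
  top <- tibble::tibble(
    selector = "correlation", learner = "linear_regression",
    model = paste0("m", 1:5), holdout_r = 0.8, n_features = 1,
    failed = FALSE, oof = noisy
  )
  x <- cbind(f1 = y + stats::rnorm(n, sd = 4))
  cv <- cv_config(seed = 13, selectors = "correlation",
                  learners = "linear_regression")
  ens <- build_ensemble(top, toy_fm(x), y, cv, support = c(40, 100))
  z <- do.call(cbind, noisy)
  stacked_mse <- mean((ens$stackers$linear_regression$predict(z) - y)^2)
  best_single_mse <- min(apply(z, 2, function(p) mean((p - y)^2)))
  expect_lt(stacked_mse, best_single_mse)
})

test_that("the weighted average and clamping follow the fixed scheme", {
  stub_stacker <- function(value) list(predict = function(z) rep(value, nrow(z)))
  base <- list(list(
    selector = "correlation", learner = "linear_regression", model = "m",
    features = "f1", fit = NULL,
    predict = function(fit, x) rep(0, nrow(x)), holdout_r = 0.5
  ))
  ens <- structure(
    list(
      base_models = base,
      stackers = list(
        linear_regression = stub_stacker(60),
        random_forest = stub_stacker(70),
        xgboost = stub_stacker(80)
      ),
      weights = c(0.25, 0.25, 0.50), support = c(0, 100),
      train_ids = character(0),
      train_oof = tibble::tibble(child_id = character(0),
                                 deep_score = numeric(0)),
      cv = cv_config()
    ),
    class = "deep_ensemble"
  )
  fm <- toy_fm(cbind(f1 = stats::rnorm(4)))
  pred <- predict_deep_scores(ens, fm)
  expect_equal(pred$deep_score, rep(0.25 * 60 + 0.25 * 70 + 0.5 * 80, 4))

  # equal stacked predictions pass through unchanged for any unit weights
  ens$stackers <- list(a = stub_stacker(66), b = stub_stacker(66),
                       c = stub_stacker(66))
  expect_equal(predict_deep_scores(ens, fm)$deep_score, rep(66, 4))

  # predictions are clamped to the score support
  ens$stackers <- list(a = stub_stacker(500), b = stub_stacker(500),
                       c = stub_stacker(500))
  expect_equal(predict_deep_scores(ens, fm)$deep_score, rep(100, 4))
})

test_that("children lacking a contributing game are excluded, not imputed", {
  base <- list(list(
    selector = "correlation", learner = "linear_regression", model = "m",
    features = c("f1", "f2"), fit = NULL,
    predict = function(fit, x) rowMeans(x), holdout_r = 0.5
  ))
  stub <- function(v) list(predict = function(z) rep(v, nrow(z)))
  ens <- structure(
    list(
      base_models = base,
      stackers = list(a = stub(70), b = stub(70), c = stub(70)),
      weights = c(0.25, 0.25, 0.5), support = c(0, 100),
      train_ids = character(0),
      train_oof = tibble::tibble(child_id = character(0),
                                 deep_score = numeric(0)),
      cv = cv_config()
    ),
    class = "deep_ensemble"
  )
  ga <- matrix(TRUE, 4, 9,
    dimnames = list(sprintf("t%03d", 1:4), deep_schema()$game_id)
  )
  ga["t002", "ms"] <- FALSE # missed the whole matching-shapes game
  ga["t003", "lr"] <- FALSE # missed a game no feature depends on
  fm <- toy_fm(
    cbind(f1 = stats::rnorm(4), f2 = stats::rnorm(4)),
    games = c("ms", "ms,jig"), games_attempted = ga
  )
  pred <- predict_deep_scores(ens, fm)
  expect_equal(attr(pred, "excluded"), "t002")
  expect_setequal(pred$child_id, c("t001", "t003", "t004"))

  ga[, "ms"] <- FALSE
  fm_all <- toy_fm(
    cbind(f1 = stats::rnorm(4), f2 = stats::rnorm(4)),
    games = c("ms", "ms,jig"), games_attempted = ga
  )
  expect_error(predict_deep_scores(ens, fm_all), "every child")
})
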