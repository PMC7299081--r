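test_that("ICC(2,1) is exact on hand-solved tables", {
  expect_equal(icc_2_1(1:5, 1:5)$icc, 1)
  # two-way ANOVA by hand: SSsubj = 10, SSrater = 2, SSerr = 0 -> 10/13
  res <- icc_2_1(c(1, 2, 3, 4), c(2, 3, 4, 5))
  expect_equal(res$icc, 10 / 13, tolerance = 1e-12)
})

test_that("ICC(2,1) matches the ANOVA oracle on random tables", {
  set.seed(1)
  for (i in 1:50) {
    x <- stats::rnorm(12, 70, 5)
    y <- x + stats::rnorm(12, 0.5, 2)
    expect_equal(icc_2_1(x, y)$icc, icc_oracle(x, y), tolerance = 1e-10)
  }
})

test_that("ICC degrades with noise and warns on zero subject variance", {
  set.seed(2)
  x <- stats::rnorm(100, 70, 5)
  iccs <- vapply(
    c(0.5, 2, 5),
    function(s) icc_2_1(x, x + stats::rnorm(100, 0, s))$icc, numeric(1)
  )
  expect_true(all(diff(iccs) < 0))
  expect_warning(res <- icc_2_1(rep(3, 10), rep(3, 10)), "zero between-subject")
  expect_equal(res$icc, 0)
})

test_that("Pearson CI reproduces the Fisher-z closed form", {
  set.seed(3)
  x <- stats::rnorm(20)
  y <- x + stats::rnorm(20)
  res <- pearson_with_ci(x, y)
  ct <- stats::cor.test(x, y)
  expect_equal(res$r, unname(ct$estimate))
  expect_equal(c(res$conf_low, res$conf_high), as.numeric(ct$conf.int),
    tolerance = 1e-10
  )
  expect_equal(pearson_with_ci(x, 2 * x + 1)$r, 1)
  # a constructed orthogonal pair has exactly zero correlation
  z <- stats::rnorm(20)
  z_orth <- as.vector(stats::resid(stats::lm(z ~ x)))
  expect_equal(pearson_with_ci(x, z_orth)$r, 0, tolerance = 1e-12)
  expect_error(pearson_with_ci(x, rep(1, 20)), "zero-variance")
})

test_that("error metrics follow their definitions and the sign convention", {
  z <- error_metrics(c(70, 72), c(70, 72))
  expect_equal(c(z$mae, z$rmse, z$bias), c(0, 0, 0))
  z <- error_metrics(c(72, 68), c(70, 70)) # errors +2, -2
  expect_equal(c(z$bias, z$mae, z$rmse), c(0, 2, 2))
  z <- error_metrics(c(71, 72, 73), c(70, 70, 70)) # errors 1, 2, 3
  expect_equal(z$mae, 2)
  expect_equal(z$rmse, sqrt(14 / 3))
  expect_equal(z$bias, 2)
  expect_lte(z$mae, z$rmse)
  # MAE <= RMSE holds for any input (Jensen)
  set.seed(4)
  for (i in 1:20) {
    a <- stats::rnorm(30)
    b <- stats::rnorm(30)
    m <- error_metrics(a, b)
    expect_lte(m$mae, m$rmse)
  }
})

test_that("Bland-Altman limits match the direct formula", {
  ba <- bland_altman_points(1:5, 1:5)
  expect_true(all(ba$points$diff == 0))
  expect_equal(unname(ba$limits), c(0, 0))
  ba <- bland_altman_points(c(4, 5, 6), c(1, 2, 3)) # constant offset 3
  expect_equal(ba$bias, 3)
  expect_equal(unname(ba$limits), c(3, 3))
  set.seed(5)
  a <- stats::rnorm(30, 70, 5)
  b <- a + stats::rnorm(30, 0, 2)
  ba <- bland_altman_points(a, b)
  d <- a - b
  expect_equal(ba$points$mean, (a + b) / 2)
  expect_equal(unname(ba$limits),
    mean(d) + c(-1.96, 1.96) * stats::sd(d)
  )
})

test_that("the Youden cutoff matches an exhaustive scan", {
  # perfectly separated classes: the midpoint of the gap is returned
  scores <- c(60, 62, 64, 72, 74, 76)
  positive <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  expect_equal(choose_cutoff(scores, positive), 68)

  set.seed(6)
  for (i in 1:50) {
    s <- round(stats::runif(12, 60, 80), 1)
    p <- stats::runif(12) < 0.4
    if (length(unique(p)) < 2) next
    cc <- choose_cutoff(s, p)
    expect_equal(youden_j(s, p, cc), cutoff_oracle_best_j(s, p),
      tolerance = 1e-12
    )
  }
  expect_error(choose_cutoff(1:4, rep(TRUE, 4)), "both classes")
  expect_warning(choose_cutoff(rep(5, 4), c(TRUE, TRUE, FALSE, FALSE)),
    "all scores equal"
  )
})

test_that("AUC equals brute-force pair counting, with ties at one half", {
  scores <- c(60, 61, 62, 63, 70, 71, 72, 73)
  positive <- c(rep(TRUE, 4), rep(FALSE, 4))
  expect_equal(roc_analysis(scores, positive, 65)$auc, 1)
  expect_equal(roc_analysis(rep(66, 8), positive, 65)$auc, 0.5)
  set.seed(7)
  for (i in 1:50) {
    s <- sample(60:75, 10, replace = TRUE)
    p <- stats::runif(10) < 0.4
    if (length(unique(p)) < 2) next
    expect_equal(roc_analysis(s, p, 66)$auc, auc_oracle(s, p),
      tolerance = 1e-12
    )
  }
  expect_error(roc_analysis(1:4, rep(FALSE, 4), 2), "single class")
})

test_that("AUC agrees with an established ROC implementation", {
  set.seed(10)
  scores <- stats::rnorm(60, 70, 5)
  positive <- scores + stats::rnorm(60, 0, 5) < 66
  ours <- roc_analysis(scores, positive, 66)$auc
  ref <- suppressMessages(as.numeric(
    pROC::auc(pROC::roc(response = positive, predictor = scores,
                        direction = ">", quiet = TRUE))
  ))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("sensitivity/specificity/accuracy are computed at the cutoff", {
  scores <- c(60, 65, 66, 70, 75)
  positive <- c(TRUE, TRUE, FALSE, FALSE, FALSE)
  r <- roc_analysis(scores, positive, cutoff = 67)
  expect_equal(r$sensitivity, 1) # 60 and 65 both below 67
  expect_equal(r$specificity, 2 / 3) # 66 is miscalled, 70 and 75 are not
  expect_equal(r$accuracy, 4 / 5)
  r66 <- roc_analysis(scores, positive, cutoff = 66)
  expect_equal(r66$specificity, 1) # a call needs a score strictly below
})

test_that("the exposure t-test matches the pooled-variance formula", {
  e <- exposure_bias_test(c(1, 2, 3, 1, 2, 3),
                          c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(e$t, 0)
  expect_equal(e$p_value, 1)
  set.seed(8)
  err <- stats::rnorm(40)
  grp <- rep(c(TRUE, FALSE), 20)
  e <- exposure_bias_test(err, grp)
  a <- err[grp]
  b <- err[!grp]
  sp <- sqrt(((length(a) - 1) * stats::var(a) + (length(b) - 1) * stats::var(b)) /
    (length(a) + length(b) - 2))
  t_hand <- (mean(a) - mean(b)) / (sp * sqrt(1 / length(a) + 1 / length(b)))
  expect_equal(e$t, t_hand, tolerance = 1e-12)
  expect_error(exposure_bias_test(err, rep(TRUE, 40)), "at least 2")
})

test_that("fine-motor correlation squares its r, including r = -0.25 exactly", {
  set.seed(9)
  fmv <- stats::rnorm(50, 50, 5)
  expect_equal(fine_motor_correlation(fmv, fmv)$r_squared, 1)
  # construct errors with exactly r = -0.25 against fine motor
  z <- stats::rnorm(50)
  z <- as.vector(stats::resid(stats::lm(z ~ fmv)))
  u <- as.vector(scale(fmv))
  err <- -0.25 * u + sqrt(1 - 0.25^2) * as.vector(scale(z))
  res <- fine_motor_correlation(err, fmv)
  expect_equal(res$r, -0.25, tolerance = 1e-12)
  expect_equal(res$r_squared, 0.0625, tolerance = 1e-12)
})

test_that("floor/ceiling counts match direct enumeration", {
  children <- tibble::tibble(
    child_id = sprintf("c%02d", 1:20),
    bsid_cognitive_raw = as.integer(c(58, 59, 60, 61, 62, rep(70, 10),
                                      84, 85, 86, 88, 89))
  )
  lp <- tibble::tibble(
    child_id = children$child_id,
    levels_played = as.integer(c(5, 9, 10, 12, 20, rep(30, 10),
                                 40, 40, 38, 40, 39))
  )
  fc <- floor_ceiling_analysis(children, lp)
  q25 <- sort(children$bsid_cognitive_raw)[ceiling(0.25 * 20)]
  q90 <- sort(children$bsid_cognitive_raw)[ceiling(0.90 * 20)]
  low <- lp$levels_played[children$bsid_cognitive_raw < q25]
  high <- lp$levels_played[children$bsid_cognitive_raw > q90]
  expect_equal(fc$n[fc$group == "low"], length(low))
  expect_equal(fc$n_lt10[fc$group == "low"], sum(low < 10)) # 9 counts, 10 not
  expect_equal(fc$n[fc$group == "high"], length(high))
  expect_equal(fc$n_not_all[fc$group == "high"], sum(high < 40))
  # everyone playing all 40 levels leaves no ceiling count
  lp$levels_played <- 40L
  fc_full <- floor_ceiling_analysis(children, lp)
  expect_equal(fc_full$n_not_all[fc_full$group == "high"], 0)
})

test_that("nearest-rank percentiles use the ceiling rule", {
  expect_equal(percentile_nearest_rank(1:100, 25), 25)
  expect_equal(percentile_nearest_rank(1:10, 25), 3)
  expect_equal(percentile_nearest_rank(c(5, 1, 9), 50), 5)
})
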