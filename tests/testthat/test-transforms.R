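test_that("sample skewness matches the adjusted Fisher-Pearson reference", {
  set.seed(1)
  for (i in 1:20) {
    x <- stats::rlnorm(30 + i)
    expect_equal(sample_skewness(x), e1071::skewness(x, type = 2),
      tolerance = 1e-12
    )
  }
  expect_true(is.na(sample_skewness(c(1, 1, 1))))
})

test_that("skew transform square-roots right-skewed and squares left-skewed columns", {
  x <- cbind(
    spike = c(rep(0, 9), 10), # strongly right-skewed
    mirror = c(rep(10, 9), 0), # its mirror image, left-skewed
    flat = 1:10 # symmetric, untouched
  )
  expect_gt(sample_skewness(x[, "spike"]), 1)
  expect_lt(sample_skewness(x[, "mirror"]), -1)
  out <- skew_transform(toy_fm(x))
  fm <- out$features
  expect_equal(out$log$transform, c("sqrt", "square", "none"))
  expect_named(fm$data, c("child_id", "spike_sqrt", "mirror_sq", "flat"))
  expect_equal(fm$data$spike_sqrt, sqrt(x[, "spike"]))
  expect_equal(fm$data$mirror_sq, x[, "mirror"]^2)
  expect_equal(fm$data$flat, x[, "flat"])
  # negative minima are shifted to zero before the square root
  y <- cbind(neg = c(rep(-5, 9), 5))
  fm2 <- skew_transform(toy_fm(y))$features
  expect_equal(fm2$data$neg_sqrt, sqrt(y[, 1] + 5))
})

test_that("correlation pruning keeps every surviving pair under the cap", {
  set.seed(2)
  x <- matrix(stats::rnorm(60 * 12), 60, 12)
  x[, 2] <- x[, 1] # duplicate: second copy must go
  x[, 5] <- x[, 4] + stats::rnorm(60, sd = 0.05) # r > 0.9 pair
  colnames(x) <- sprintf("f%02d", 1:12)
  fm <- prune_correlated(toy_fm(x))
  kept <- fm$meta$name
  expect_false("f02" %in% kept)
  expect_true("f01" %in% kept)
  expect_false("f05" %in% kept)
  cm <- abs(stats::cor(fm_matrix(fm)))
  diag(cm) <- 0
  expect_lt(max(cm), 0.9)

  # mutually orthogonal columns all survive
  z <- qr.Q(qr(matrix(stats::rnorm(40 * 5), 40, 5)))
  colnames(z) <- paste0("q", 1:5)
  expect_equal(nrow(prune_correlated(toy_fm(z))$meta), 5)
})

test_that("zero-variance columns are retained with a warning", {
  x <- cbind(a = rnorm(20), const = rep(3, 20))
  expect_warning(fm <- prune_correlated(toy_fm(x)), "zero-variance")
  expect_true("const" %in% fm$meta$name)
})

test_that("interactions form distinct-pair products and both ratios", {
  set.seed(3)
  x <- cbind(a = stats::runif(50, 1, 2), b = stats::runif(50, 1, 2))
  fm <- build_interactions(toy_fm(x), subset = c("a", "b"))
  new <- fm$meta$name[fm$meta$stage == "interaction"]
  expect_true(all(new %in% c("a_times_b", "a_div_by_b", "b_div_by_a")))
  expect_lte(length(new), 3)
  expect_false(any(grepl("a_times_a|b_times_b", fm$meta$name)))
  expect_equal(fm$data$a_times_b, x[, "a"] * x[, "b"])
})

test_that("ratio candidates with too many zero denominators are excluded", {
  set.seed(4)
  den <- c(rep(0, 10), stats::runif(40, 1, 2)) # 20% zero denominators
  x <- cbind(num = stats::rnorm(50), den = den)
  fm <- build_interactions(toy_fm(x), subset = c("num", "den"))
  expect_false("num_div_by_den" %in% fm$meta$name)
})

test_that("interaction survivors stay uncorrelated with the existing set", {
  set.seed(5)
  a <- stats::runif(80, 1, 3)
  x <- cbind(a = a, b = a * 2 + stats::rnorm(80, sd = 0.01), c = stats::rnorm(80))
  fm <- build_interactions(toy_fm(x), subset = c("a", "b", "c"))
  new <- fm$meta$name[fm$meta$stage == "interaction"]
  if (length(new) > 0) {
    cm <- abs(stats::cor(fm_matrix(fm)))
    diag(cm) <- 0
    expect_lt(max(cm[new, fm$meta$name[fm$meta$stage != "interaction"]]), 0.9)
  }
  expect_error(build_interactions(toy_fm(x), subset = c("a", "zz")), "absent")
})

test_that("mas-o-menos equals the hand-computed sign-weighted mean", {
  set.seed(6)
  n <- 40
  y <- stats::rnorm(n)
  x <- cbind(
    p1 = y + stats::rnorm(n), # positive association
    p2 = y + stats::rnorm(n),
    m1 = -y + stats::rnorm(n) # negative association
  )
  fm <- mas_o_menos(toy_fm(x), y)
  z <- scale(x)
  w <- sign(stats::cor(x, y))
  by_hand <- as.vector(z %*% as.vector(w)) / 3
  expect_equal(fm$data$mom, by_hand, tolerance = 1e-12)

  # a single positively-correlated column: mom is that column standardized
  fm1 <- mas_o_menos(toy_fm(x[, "p1", drop = FALSE]), y)
  expect_equal(fm1$data$mom, as.vector(scale(x[, "p1"])), tolerance = 1e-12)
  # duplicating it leaves mom unchanged
  fm2 <- mas_o_menos(toy_fm(cbind(p1 = x[, "p1"], p1b = x[, "p1"])), y)
  expect_equal(fm2$data$mom, fm1$data$mom, tolerance = 1e-12)
})

test_that("PCA keeps the fewest components reaching the variance target", {
  # two perfectly correlated columns collapse to one component
  set.seed(7)
  a <- stats::rnorm(50)
  fm <- pca_features(toy_fm(cbind(a = a, b = 2 * a)), var_target = 0.70)
  expect_equal(attr(fm, "pca_fit")$n_components, 1)

  # isotropic 4-column noise: three ~25% components are needed for 70%
  x <- matrix(stats::rnorm(2000 * 4), 2000, 4)
  colnames(x) <- paste0("n", 1:4)
  fm2 <- pca_features(toy_fm(x), var_target = 0.70)
  ev <- eigen(stats::cov(scale(x)), symmetric = TRUE)$values
  m_oracle <- which(cumsum(ev) / sum(ev) >= 0.70)[1]
  expect_equal(attr(fm2, "pca_fit")$n_components, m_oracle)
  expect_equal(m_oracle, 3L)
})

test_that("training-only fits leak nothing from held-out rows", {
  set.seed(8)
  x <- matrix(stats::rnorm(60 * 8), 60, 8)
  colnames(x) <- paste0("f", 1:8)
  fm <- toy_fm(x)
  train <- fm$data$child_id[1:40]
  y <- stats::rnorm(40)

  perturbed <- fm
  test_rows <- 41:60
  for (j in colnames(x)) {
    perturbed$data[[j]][test_rows] <-
      sample(perturbed$data[[j]][test_rows]) + 100
  }
  m1 <- mas_o_menos(fm, y, fit_ids = train)
  m2 <- mas_o_menos(perturbed, y, fit_ids = train)
  expect_equal(attr(m1, "mom_fit"), attr(m2, "mom_fit"))
  expect_equal(m1$data$mom[1:40], m2$data$mom[1:40])

  p1 <- pca_features(fm, fit_ids = train)
  p2 <- pca_features(perturbed, fit_ids = train)
  expect_equal(attr(p1, "pca_fit")$rotation, attr(p2, "pca_fit")$rotation)

  s1 <- skew_transform(fm, fit_ids = train)
  s2 <- skew_transform(perturbed, fit_ids = train)
  expect_equal(s1$log, s2$log)
})

test_that("assembly is deterministic and its bookkeeping adds up", {
  cohort <- small_cohort()
  split <- split_train_test(cohort, cv_config(seed = 3))
  fm1 <- assemble_feature_set(cohort, train_ids = split$train_ids)
  fm2 <- assemble_feature_set(cohort, train_ids = split$train_ids)
  expect_equal(fm1$data, fm2$data)
  rep <- feature_report(fm1)
  n <- function(stage) rep$n_features[rep$stage == stage]
  expect_equal(
    n("total"), n("pruned") + n("interaction") + n("mom") + n("pca")
  )
  expect_equal(nrow(fm1$meta), n("total"))
  expect_length(attr(fm1, "interaction_subset"), 20)
  # scaled training columns have mean 0, sd 1
  xtr <- fm_matrix(playcog:::fm_filter(fm1, split$train_ids))
  expect_lt(max(abs(colMeans(xtr))), 1e-8)
  sds <- apply(xtr, 2, stats::sd)
  expect_lt(max(abs(sds[sds > 0] - 1)), 1e-8)
})
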