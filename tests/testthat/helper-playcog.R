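# shared fixtures, all generated in code

ev_tbl <- function(t, outcome, gesture = "tap") {
  tibble::tibble(t_ms = t, gesture = gesture, outcome = outcome)
}

make_session <- function(child, game, level, events = ev_tbl(numeric(0), character(0)),
                         attempted = TRUE, completed = FALSE) {
  tibble::tibble(
    child_id = child, game_id = game, level = as.integer(level),
    attempted = attempted, completed = completed, events = list(events)
  )
}

# minimal deep_features wrapper around a plain numeric matrix
toy_fm <- function(x, games = rep("", ncol(x)), stage = "derived",
                   games_attempted = NULL) {
  n <- nrow(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  ids <- sprintf("t%03d", seq_len(n))
  data <- tibble::tibble(child_id = ids)
  for (j in seq_len(ncol(x))) data[[colnames(x)[j]]] <- x[, j]
  meta <- tibble::tibble(
    name = colnames(x), game_scope = games, level_scope = "",
    feature_type = "count", stage = stage, transform = "none", games = games
  )
  mask <- matrix(FALSE, n, ncol(x), dimnames = list(ids, colnames(x)))
  if (is.null(games_attempted)) {
    games_attempted <- matrix(
      TRUE, n, 9, dimnames = list(ids, deep_schema()$game_id)
    )
  }
  playcog:::new_deep_features(data, meta, mask, games_attempted)
}

# lazily computed shared objects (helpers run once per test session)
.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

small_cohort <- function() {
  memo("small_cohort", simulate_cohort(sim_config(n_children = 60, seed = 2)))
}

# a compact but complete pipeline run over the full selector x learner grid
mini_run <- function() {
  memo("mini_run", {
    run_pipeline(
      sim = sim_config(n_children = 60, seed = 2),
      cv = cv_config(k_folds = 4, repeats = 1, seed = 5)
    )
  })
}

# idealized validation regimes (see the methods vignette)
recovery_sim_config <- function(n = 200, seed = 7) {
  sim_config(
    n_children = n, seed = seed,
    game_discrimination = c(
      st = 2, at = 2, pb = 2, gg = 2, ho = 2, oo = 2, ms = 2, jig = 2, lr = 2
    ),
    response_noise = 0.4,
    tempo = list(mean_gap_s = 2, theta_slope = 0.4, sdlog = 0.3,
                 min_gap_s = 0.25),
    background_rate = 0.02,
    outcome_map = list(mu = 70, sigma_y = 6, rho = 0.995)
  )
}

null_sim_config <- function(n = 200, seed = 1) {
  sim_config(
    n_children = n, seed = seed,
    outcome_map = list(mu = 70, sigma_y = 6, rho = 0)
  )
}

cheap_cv_config <- function(seed = 1) {
  cv_config(
    k_folds = 5, repeats = 1, seed = seed,
    selectors = c("correlation", "lasso", "mrmr"),
    learners = c("linear_regression", "svm")
  )
}

# independent ICC(2,1) oracle via a fixed-effects two-way ANOVA fit
icc_oracle <- function(x, y) {
  n <- length(x)
  d <- data.frame(
    score = c(x, y),
    subj = factor(rep(seq_len(n), 2)),
    rater = factor(rep(1:2, each = n))
  )
  ms <- stats::anova(stats::lm(score ~ subj + rater, data = d))[["Mean Sq"]]
  msr <- ms[1]
  msc <- ms[2]
  mse <- ms[3]
  (msr - mse) / (msr + mse + 2 * (msc - mse) / n)
}

# brute-force AUC by counting positive/negative pairs
auc_oracle <- function(scores, positive) {
  dp <- scores[positive]
  dn <- scores[!positive]
  total <- 0
  for (a in dp) total <- total + sum(a < dn) + 0.5 * sum(a == dn)
  total / (length(dp) * length(dn))
}

# exhaustive Youden scan over a dense candidate set
cutoff_oracle_best_j <- function(scores, positive) {
  u <- sort(unique(scores))
  cand <- sort(unique(c(u - 1e-9, u + 1e-9, (u[-length(u)] + u[-1]) / 2,
                        u[1] - 1, u[length(u)] + 1)))
  j <- vapply(cand, function(cc) {
    mean(scores[positive] < cc) + mean(scores[!positive] >= cc)
  }, numeric(1))
  max(j)
}

youden_j <- function(scores, positive, cutoff) {
  mean(scores[positive] < cutoff) + mean(scores[!positive] >= cutoff)
}
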