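#' Simulation configuration for synthetic cohorts
#'
#' Builds the configuration of the cohort generator. The generative model is
#' a latent-ability model: each child carries an ability \eqn{\theta \sim
#' N(0, \mathrm{ability\_sd}^2)} that drives (i) whether a game is attempted
#' at all, (ii) the probability that a gesture is correct, (iii) the tempo of
#' gestures, and (iv) the benchmark cognitive and fine-motor scores.
#'
#' Key defaults encode the study conditions the cohort emulates: the
#' engagement intercept/slope are calibrated so that about 95.5% of children
#' attempt all nine games, the smartphone-exposure probability is 0.57, and
#' the integer benchmark score lives on a 31-point raw-score support
#' (default 57--88).
#'
#' @param n_children Number of children to simulate.
#' @param seed Integer seed; cohorts are reproducible seed-for-seed.
#' @param ability_sd Standard deviation of latent ability.
#' @param game_discrimination Named per-game slope of correctness on ability.
#' @param level_difficulty `c(intercept, slope)`: the logit offset of level
#'   `k` is `intercept + slope * (k - 1)`, so later levels are harder.
#' @param response_noise Scale dividing the correctness logit; as it
#'   approaches 0 correctness becomes a deterministic step in ability.
#' @param tempo List with `mean_gap_s` (median inter-gesture gap at
#'   ability 0), `theta_slope` (log-scale speed-up per ability unit),
#'   `sdlog` (lognormal dispersion; 0 gives fixed gaps) and `min_gap_s`.
#' @param background_rate Probability that a gesture is an off-target
#'   "background" event rather than a scored response.
#' @param engagement `c(intercept, slope)`: P(attempt a game) =
#'   `plogis(intercept + slope * theta)`.
#' @param outcome_map List with `mu`, `sigma_y`, `rho`: the benchmark score
#'   is `round(clamp(mu + sigma_y * (rho * theta + sqrt(1 - rho^2) * eps)))`
#'   on `support`.
#' @param support Integer score range, `max - min` must equal 31.
#' @param fine_motor List with `mu`, `sigma`, `rho` for the fine-motor score.
#' @param exposure_prob Probability of prior smartphone exposure,
#'   independent of gameplay.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_children = 200,
                       seed = 1,
                       ability_sd = 1,
                       game_discrimination = c(
                         st = 0.8, at = 0.9, pb = 1.0, gg = 1.1, ho = 1.2,
                         oo = 1.2, ms = 1.3, jig = 1.3, lr = 1.1
                       ),
                       level_difficulty = c(intercept = -1.2, slope = 0.55),
                       response_noise = 1,
                       tempo = list(
                         mean_gap_s = 2, theta_slope = 0.25,
                         sdlog = 0.5, min_gap_s = 0.25
                       ),
                       background_rate = 0.10,
                       engagement = c(intercept = 6.887663, slope = 2.0),
                       outcome_map = list(mu = 70, sigma_y = 6, rho = 0.75),
                       support = c(57L, 88L),
                       fine_motor = list(mu = 50, sigma = 5, rho = 0.5),
                       exposure_prob = 0.57) {
  config <- list(
    n_children = n_children, seed = seed, ability_sd = ability_sd,
    game_discrimination = game_discrimination,
    level_difficulty = level_difficulty, response_noise = response_noise,
    tempo = tempo, background_rate = background_rate,
    engagement = engagement, outcome_map = outcome_map,
    support = as.integer(support), fine_motor = fine_motor,
    exposure_prob = exposure_prob
  )
  validate_sim_config(config)
}

validate_sim_config <- function(config) {
  stopifnot(
    "n_children must be a positive count" =
      rlang::is_scalar_integerish(config$n_children) && config$n_children >= 1,
    "ability_sd must be non-negative" = config$ability_sd >= 0,
    "response_noise must be non-negative" = config$response_noise >= 0,
    "background_rate must be in [0, 1]" =
      config$background_rate >= 0 && config$background_rate <= 1,
    "exposure_prob must be in [0, 1]" =
      config$exposure_prob >= 0 && config$exposure_prob <= 1
  )
  rho <- config$outcome_map$rho
  if (is.null(rho) || rho < 0 || rho > 1) {
    stop("outcome_map$rho must lie in [0, 1]", call. = FALSE)
  }
  if (diff(range(config$support)) != 31L) {
    stop("score support must span exactly 31 points, got ",
      diff(range(config$support)),
      call. = FALSE
    )
  }
  fm_rho <- config$fine_motor$rho
  if (is.null(fm_rho) || abs(fm_rho) > 1) {
    stop("fine_motor$rho must lie in [-1, 1]", call. = FALSE)
  }
  structure(config, class = "sim_config")
}

#' Simulate a synthetic cohort
#'
#' Draws `n_children` latent abilities, generates ability-graded gameplay
#' event logs over the full battery with [generate_gameplay()], and
#' benchmark outcomes with [generate_outcomes()]. Deterministic given
#' `config$seed`.
#'
#' @param config A [sim_config()].
#' @param schema Game schema (defaults to the built-in battery).
#' @return A `deep_cohort`: list with `children` (one row per child,
#'   including `latent_ability`), `sessions` (attempted level sessions with
#'   an `events` list-column), `config`, and `schema`.
#' @examples
#' cohort <- simulate_cohort(sim_config(n_children = 5, seed = 1))
#' cohort$children
#' @export
simulate_cohort <- function(config = sim_config(), schema = deep_schema()) {
  config <- validate_sim_config(config)
  schema <- validate_schema(schema)
  set.seed(config$seed)
  n <- config$n_children
  child_id <- sprintf("c%05d", seq_len(n))
  theta <- stats::rnorm(n, 0, config$ability_sd)
  age_months <- pmin(40, pmax(34, stats::rnorm(n, 37.3, 0.9)))
  sex <- sample(c("female", "male"), n, replace = TRUE, prob = c(0.515, 0.485))
  preschool <- sample(c("none", "private", "anganwadi"), n,
    replace = TRUE, prob = c(0.51, 0.31, 0.18)
  )
  outcomes <- generate_outcomes(theta, config)
  children <- tibble::tibble(
    child_id = child_id,
    age_months = age_months,
    sex = sex,
    smartphone_exposure = outcomes$smartphone_exposure,
    preschool = preschool,
    bsid_cognitive_raw = outcomes$bsid_cognitive_raw,
    bsid_fine_motor = outcomes$bsid_fine_motor,
    latent_ability = theta
  )
  sessions <- generate_gameplay(theta, schema, config, child_id = child_id)
  structure(
    list(children = children, sessions = sessions, config = config,
         schema = schema),
    class = "deep_cohort"
  )
}

#' @export
print.deep_cohort <- function(x, ...) {
  cat(
    "<deep_cohort> ", nrow(x$children), " children, ",
    nrow(x$sessions), " level sessions (seed ", x$config$seed, ")\n",
    sep = ""
  )
  invisible(x)
}

#' Generate benchmark outcomes from latent ability
#'
#' The benchmark cognitive score is a linear-Gaussian map of ability,
#' rounded and clamped to the integer support; the fine-motor score is the
#' analogous (unrounded) map; smartphone exposure is Bernoulli and
#' independent of ability and of gameplay.
#'
#' @param theta Vector of latent abilities (on the ability_sd = 1 scale).
#' @param config A [sim_config()].
#' @return Tibble with `bsid_cognitive_raw` (integer), `bsid_fine_motor`,
#'   `smartphone_exposure`.
#' @export
generate_outcomes <- function(theta, config = sim_config()) {
  om <- config$outcome_map
  eps <- stats::rnorm(length(theta))
  z <- om$rho * theta + sqrt(1 - om$rho^2) * eps
  raw <- round(om$mu + om$sigma_y * z)
  bsid <- as.integer(pmin(max(config$support), pmax(min(config$support), raw)))
  fm <- config$fine_motor
  eps2 <- stats::rnorm(length(theta))
  fine <- fm$mu + fm$sigma * (fm$rho * theta + sqrt(1 - fm$rho^2) * eps2)
  tibble::tibble(
    bsid_cognitive_raw = bsid,
    bsid_fine_motor = round(fine, 1),
    smartphone_exposure = stats::runif(length(theta)) < config$exposure_prob
  )
}

#' Generate gameplay event logs for a vector of abilities
#'
#' For each child and game, the game is attempted with probability
#' `plogis(engagement)` increasing in ability. Within an attempted game,
#' level 1 is always attempted and level `k + 1` only if level `k` was
#' completed. Within a level, gestures arrive with lognormal inter-event
#' gaps (faster for abler children); each gesture is a background event with
#' probability `background_rate`, otherwise correct with probability
#' `plogis((discrimination * theta - difficulty) / response_noise)`. A level
#' completes when `advance_threshold` correct responses occur before the
#' level timer; events stop at completion or at the timer.
#'
#' Uses the current RNG state; seed upstream (e.g. via [simulate_cohort()])
#' for reproducibility.
#'
#' @param theta Vector of latent abilities.
#' @param schema Game schema.
#' @param config A [sim_config()].
#' @param child_id Optional character ids, defaults to `c00001`, ...
#' @return A session tibble of attempted levels only (unattempted levels are
#'   simply absent), valid under [validate_sessions()].
#' @export
generate_gameplay <- function(theta, schema = deep_schema(),
                              config = sim_config(),
                              child_id = sprintf("c%05d", seq_along(theta))) {
  schema <- validate_schema(schema)
  n <- length(theta)
  grid <- schema_level_grid(schema)
  grid <- tidyr::crossing(
    tibble::tibble(child_id = child_id, theta = theta),
    grid
  )
  grid <- dplyr::arrange(grid, .data$child_id, .data$game_id, .data$level)
  m <- nrow(grid)

  # per-(child, game) attempt flags, increasing in ability
  eng <- config$engagement
  cg <- dplyr::distinct(grid, .data$child_id, .data$game_id, .data$theta)
  cg$game_attempted <-
    stats::runif(nrow(cg)) < stats::plogis(eng[["intercept"]] + eng[["slope"]] * cg$theta)
  grid <- dplyr::left_join(
    grid, cg[, c("child_id", "game_id", "game_attempted")],
    by = c("child_id", "game_id")
  )

  disc <- config$game_discrimination[grid$game_id]
  diff_l <- config$level_difficulty[["intercept"]] +
    config$level_difficulty[["slope"]] * (grid$level - 1)
  logit <- disc * grid$theta - diff_l
  p_correct <- if (config$response_noise > 0) {
    stats::plogis(logit / config$response_noise)
  } else {
    as.numeric(logit > 0) + 0.5 * (logit == 0)
  }

  # event block: gaps, times, outcomes for every candidate level at once
  n_ev <- 120L
  tempo <- config$tempo
  meanlog <- log(tempo$mean_gap_s) - tempo$theta_slope * grid$theta
  gaps <- matrix(
    stats::rlnorm(m * n_ev, meanlog = rep(meanlog, n_ev), sdlog = tempo$sdlog),
    nrow = m
  )
  gaps <- pmax(gaps, tempo$min_gap_s)
  cum_upper <- upper.tri(diag(n_ev), diag = TRUE)
  times <- gaps %*% cum_upper
  in_timer <- times <= grid$level_timer_s
  is_bg <- matrix(stats::runif(m * n_ev) < config$background_rate, nrow = m)
  is_correct <- !is_bg &
    matrix(stats::runif(m * n_ev) < rep(p_correct, n_ev), nrow = m)
  corr_counted <- (is_correct & in_timer) * 1
  cum_correct <- corr_counted %*% cum_upper
  comp_idx <- rowSums(cum_correct < grid$advance_threshold) + 1L
  grid$completed <- comp_idx <= n_ev
  grid$n_keep <- ifelse(grid$completed, comp_idx, rowSums(in_timer))

  # a level is attempted iff its game is and every earlier level completed
  grid <- dplyr::mutate(
    dplyr::group_by(grid, .data$child_id, .data$game_id),
    attempted = .data$game_attempted &
      cumprod(dplyr::lag(.data$completed, default = TRUE)) > 0
  )
  grid <- dplyr::ungroup(grid)
  grid$completed <- grid$completed & grid$attempted

  # materialize events for attempted rows only
  rows <- which(grid$attempted & grid$n_keep > 0)
  events <- rep(list(empty_events()), m)
  if (length(rows) > 0) {
    counts <- grid$n_keep[rows]
    row_rep <- rep(rows, counts)
    col_idx <- sequence(counts)
    flat <- cbind(row_rep, col_idx)
    gest_game <- grid$gesture[row_rep]
    gesture <- ifelse(
      gest_game == "mixed",
      sample(c("tap", "drag"), length(row_rep), replace = TRUE),
      ifelse(gest_game == "drag", "drag", "tap")
    )
    ev_long <- tibble::tibble(
      t_ms = round(times[flat] * 1000),
      gesture = gesture,
      outcome = dplyr::case_when(
        is_bg[flat] ~ "background",
        is_correct[flat] ~ "correct",
        .default = "incorrect"
      )
    )
    pieces <- vctrs::vec_split(ev_long, row_rep)
    events[pieces$key] <- pieces$val
  }
  grid$events <- events

  out <- grid[grid$attempted, c(
    "child_id", "game_id", "level", "attempted", "completed", "events"
  )]
  out$level <- as.integer(out$level)
  tibble::as_tibble(out)
}

#' Write a simulated cohort to disk
#'
#' Writes the event logs (JSON-lines), the child table (CSV) and the
#' resolved simulation configuration (YAML) into a directory.
#'
#' @param cohort A `deep_cohort`.
#' @param dir Output directory, created if absent.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_event_logs(cohort$sessions, file.path(dir, "events.jsonl"),
    schema = cohort$schema
  )
  write_child_table(cohort$children, file.path(dir, "children.csv"))
  yaml::write_yaml(unclass(cohort$config), file.path(dir, "sim_config.yaml"))
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir Cohort directory.
#' @param schema Game schema used to validate the event logs.
#' @return A `deep_cohort` (its `config` is the resolved YAML as a list).
#' @export
read_cohort <- function(dir, schema = deep_schema()) {
  structure(
    list(
      children = read_child_table(file.path(dir, "children.csv")),
      sessions = read_event_logs(file.path(dir, "events.jsonl"), schema),
      config = yaml::read_yaml(file.path(dir, "sim_config.yaml")),
      schema = schema
    ),
    class = "deep_cohort"
  )
}
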