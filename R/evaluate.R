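#' Intraclass correlation ICC(2,1) with 95% confidence interval
#'
#' Single-measures, absolute-agreement intraclass correlation from the
#' two-way random-effects ANOVA with subjects and methods (k = 2 raters:
#' the two scores) as random factors, after Shrout & Fleiss. The interval
#' is the standard F-based one with Satterthwaite degrees of freedom.
#'
#' @param x,y Paired score vectors (the two "raters").
#' @param conf_level Confidence level (default 0.95).
#' @return Tibble with `icc`, `conf_low`, `conf_high`, `n`.
#' @export
icc_2_1 <- function(x, y, conf_level = 0.95) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  n <- length(x)
  k <- 2
  m <- cbind(x, y)
  gm <- mean(m)
  ss_rows <- k * sum((rowMeans(m) - gm)^2)
  ss_cols <- n * sum((colMeans(m) - gm)^2)
  ss_err <- sum((m - gm)^2) - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  if (msr <= .Machine$double.eps * abs(gm)) {
    warning("zero between-subject variance; ICC reported as 0")
    return(tibble::tibble(icc = 0, conf_low = NA_real_,
                          conf_high = NA_real_, n = n))
  }
  icc <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  alpha <- 1 - conf_level
  a <- k * icc / (n * (1 - icc))
  b <- 1 + k * icc * (n - 1) / (n * (1 - icc))
  v <- (a * msc + b * mse)^2 /
    ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
  f_l <- stats::qf(1 - alpha / 2, n - 1, v)
  f_u <- stats::qf(1 - alpha / 2, v, n - 1)
  lower <- n * (msr - f_l * mse) /
    (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
  upper <- n * (f_u * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * f_u * msr)
  tibble::tibble(icc = icc, conf_low = lower, conf_high = upper, n = n)
}

#' Pearson correlation with Fisher-z confidence interval
#'
#' @param x,y Paired vectors (n >= 4, both non-constant).
#' @param conf_level Confidence level (default 0.95).
#' @return Tibble with `r`, `conf_low`, `conf_high`, `n`.
#' @export
pearson_with_ci <- function(x, y, conf_level = 0.95) {
  stopifnot(length(x) == length(y), length(x) >= 4)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined for a zero-variance input", call. = FALSE)
  }
  n <- length(x)
  r <- stats::cor(x, y)
  z <- atanh(r)
  se <- 1 / sqrt(n - 3)
  q <- stats::qnorm(1 - (1 - conf_level) / 2)
  tibble::tibble(
    r = r, conf_low = tanh(z - q * se), conf_high = tanh(z + q * se), n = n
  )
}

#' Prediction-error metrics
#'
#' Errors follow the DEEP - benchmark sign convention, so a positive mean
#' bias means over-prediction. The RMSE's dispersion is reported as the
#' square root of the SD of the per-child squared errors.
#'
#' @param deep Predicted scores.
#' @param bsid Benchmark scores.
#' @return Tibble with `mae`, `mae_sd`, `rmse`, `rmse_sd`, `bias`,
#'   `bias_sd`, `n`.
#' @export
error_metrics <- function(deep, bsid) {
  stopifnot(length(deep) == length(bsid), length(deep) > 0)
  err <- deep - bsid
  tibble::tibble(
    mae = mean(abs(err)), mae_sd = stats::sd(abs(err)),
    rmse = sqrt(mean(err^2)), rmse_sd = sqrt(stats::sd(err^2)),
    bias = mean(err), bias_sd = stats::sd(err),
    n = length(err)
  )
}

#' Bland-Altman agreement points and limits
#'
#' @param deep,bsid Paired scores.
#' @return List with `points` (tibble of per-child `mean` and `diff` =
#'   deep - bsid), `bias`, and `limits` (bias +/- 1.96 SD of differences).
#' @export
bland_altman_points <- function(deep, bsid) {
  stopifnot(length(deep) == length(bsid))
  d <- deep - bsid
  bias <- mean(d)
  s <- stats::sd(d)
  if (is.na(s)) s <- 0
  list(
    points = tibble::tibble(mean = (deep + bsid) / 2, diff = d),
    bias = bias,
    limits = c(lower = bias - 1.96 * s, upper = bias + 1.96 * s)
  )
}

#' Youden-style cutoff on the training scores
#'
#' Scans the midpoints between consecutive sorted unique scores (plus
#' sentinels below and above the range); a child is called positive when
#' their score falls below the cutoff. Returns the cutoff maximizing
#' sensitivity + specificity; ties take the lowest cutoff.
#'
#' @param scores Predicted scores on the training set.
#' @param positive Logical flags (TRUE = below-percentile benchmark).
#' @return A single cutoff value.
#' @export
choose_cutoff <- function(scores, positive) {
  stopifnot(length(scores) == length(positive))
  if (length(unique(positive)) < 2) {
    stop("both classes must be present to choose a cutoff", call. = FALSE)
  }
  u <- sort(unique(scores))
  if (length(u) == 1) {
    warning("all scores equal; degenerate cutoff at the single value")
    return(u)
  }
  cand <- c(u[1] - 1, (u[-length(u)] + u[-1]) / 2, u[length(u)] + 1)
  j <- vapply(cand, function(cc) {
    sens <- mean(scores[positive] < cc)
    spec <- mean(scores[!positive] >= cc)
    sens + spec
  }, numeric(1))
  cand[which.max(j)] # which.max takes the first, i.e. lowest, maximizer
}

#' ROC analysis of low-scorer discrimination
#'
#' The positive class is "benchmark score below the reference 25th
#' percentile"; lower predicted scores indicate positivity. AUC uses the
#' Mann-Whitney pair-counting construction (ties count 1/2);
#' sensitivity/specificity/accuracy are computed at the supplied cutoff
#' (positive call = score strictly below the cutoff).
#'
#' @param deep Predicted scores.
#' @param positive Logical positive-class flags.
#' @param cutoff Score cutoff (from [choose_cutoff()] on the training set).
#' @return Tibble with `cutoff`, `sensitivity`, `specificity`, `auc`,
#'   `accuracy`, `n_positive`, `n`.
#' @export
roc_analysis <- function(deep, positive, cutoff) {
  stopifnot(length(deep) == length(positive))
  if (length(unique(positive)) < 2) {
    stop("AUC undefined with a single class", call. = FALSE)
  }
  n_pos <- sum(positive)
  n_neg <- sum(!positive)
  # rank on -score: higher rank = stronger evidence of positivity
  rk <- rank(-deep)
  auc <- (sum(rk[positive]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  pred_pos <- deep < cutoff
  tibble::tibble(
    cutoff = cutoff,
    sensitivity = mean(pred_pos[positive]),
    specificity = mean(!pred_pos[!positive]),
    auc = auc,
    accuracy = mean(pred_pos == positive),
    n_positive = n_pos,
    n = length(deep)
  )
}

#' Prediction-error bias by prior smartphone exposure
#'
#' Student's unpaired t-test with equal variances comparing mean
#' prediction error between exposed and unexposed children.
#'
#' @param errors Per-child prediction errors (DEEP - benchmark).
#' @param exposure Logical exposure flags.
#' @return Tibble with `t`, `p_value`, `mean_exposed`, `mean_unexposed`,
#'   `n_exposed`, `n_unexposed`.
#' @export
exposure_bias_test <- function(errors, exposure) {
  stopifnot(length(errors) == length(exposure))
  if (sum(exposure) < 2 || sum(!exposure) < 2) {
    stop("each exposure group needs at least 2 children", call. = FALSE)
  }
  tt <- stats::t.test(errors[exposure], errors[!exposure], var.equal = TRUE)
  tibble::tibble(
    t = unname(tt$statistic), p_value = tt$p.value,
    mean_exposed = mean(errors[exposure]),
    mean_unexposed = mean(errors[!exposure]),
    n_exposed = sum(exposure), n_unexposed = sum(!exposure)
  )
}

#' Correlation of prediction errors with fine-motor scores
#'
#' @param errors Prediction errors (DEEP - benchmark).
#' @param fine_motor Fine-motor benchmark scores.
#' @return Tibble with `r`, `conf_low`, `conf_high`, `r_squared`, `n`.
#' @export
fine_motor_correlation <- function(errors, fine_motor) {
  res <- pearson_with_ci(errors, fine_motor)
  res$r_squared <- res$r^2
  res
}

#' Floor/ceiling analysis of levels played
#'
#' Compares how many difficulty levels low-scoring (< `pct_low`-th
#' percentile) and high-scoring (> `pct_high`-th percentile) children
#' attempted. Headline counts: low scorers who played fewer than 10 levels
#' (floor) and high scorers who did not attempt all levels (ceiling).
#' Percentiles are nearest-rank on the benchmark scores.
#'
#' @param children Child tibble with `bsid_cognitive_raw`.
#' @param levels_played Tibble from [levels_played_per_child()].
#' @param pct_low,pct_high Percentile bounds (defaults 25 and 90).
#' @param max_levels Battery total (default 40).
#' @return Tibble with one row per group: `group`, `n`, `n_lt10`,
#'   `n_not_all`, and the `levels` distribution as a list-column.
#' @export
floor_ceiling_analysis <- function(children, levels_played, pct_low = 25,
                                   pct_high = 90, max_levels = 40) {
  df <- dplyr::inner_join(children, levels_played, by = "child_id")
  q_low <- percentile_nearest_rank(df$bsid_cognitive_raw, pct_low)
  q_high <- percentile_nearest_rank(df$bsid_cognitive_raw, pct_high)
  groups <- list(
    low = df$levels_played[df$bsid_cognitive_raw < q_low],
    high = df$levels_played[df$bsid_cognitive_raw > q_high]
  )
  out <- purrr::imap(groups, function(lv, nm) {
    if (length(lv) == 0) {
      warning("empty ", nm, " group omitted from floor/ceiling analysis")
      return(NULL)
    }
    tibble::tibble(
      group = nm, n = length(lv),
      n_lt10 = sum(lv < 10), n_not_all = sum(lv < max_levels),
      levels = list(lv)
    )
  })
  purrr::list_rbind(purrr::compact(out))
}

#' Evaluate ensemble predictions against the benchmark
#'
#' Assembles the full evaluation surface: agreement metrics (Pearson with
#' Fisher CI, ICC(2,1) with F-based CI, MAE/RMSE/bias with SDs) separately
#' for training and test children; ROC metrics at a Youden-style cutoff
#' chosen on the training set against the below-25th-percentile flag
#' (percentile frozen on the training children); exposure and fine-motor
#' bias checks on all predicted children; and the floor/ceiling analysis.
#'
#' @param predictions Tibble from [predict_deep_scores()].
#' @param cohort The evaluated `deep_cohort`.
#' @param train_ids Training child ids from [split_train_test()].
#' @param pct_low Percentile defining the positive (delay-risk) class.
#' @return A `deep_evaluation` list of tibbles: `agreement`, `roc`,
#'   `exposure`, `fine_motor`, `floor_ceiling`, plus `cutoff`,
#'   `bsid_threshold`, `excluded`, and the joined per-child `scores`.
#' @export
deep_evaluate <- function(predictions, cohort, train_ids, pct_low = 25) {
  scores <- dplyr::inner_join(
    predictions, cohort$children, by = "child_id"
  )
  scores$split <- ifelse(scores$child_id %in% train_ids, "train", "test")
  scores$error <- scores$deep_score - scores$bsid_cognitive_raw

  agreement <- purrr::map(c(train = "train", test = "test"), function(sp) {
    s <- scores[scores$split == sp, ]
    dplyr::bind_cols(
      tibble::tibble(split = sp),
      stats::setNames(
        pearson_with_ci(s$deep_score, s$bsid_cognitive_raw)[, 1:3],
        c("pearson_r", "pearson_low", "pearson_high")
      ),
      stats::setNames(
        icc_2_1(s$deep_score, s$bsid_cognitive_raw)[, 1:3],
        c("icc", "icc_low", "icc_high")
      ),
      error_metrics(s$deep_score, s$bsid_cognitive_raw)
    )
  })
  agreement <- purrr::list_rbind(agreement)

  train_scores <- scores[scores$split == "train", ]
  bsid_threshold <- percentile_nearest_rank(
    train_scores$bsid_cognitive_raw, pct_low
  )
  scores$positive <- scores$bsid_cognitive_raw < bsid_threshold
  cutoff <- choose_cutoff(
    train_scores$deep_score,
    train_scores$bsid_cognitive_raw < bsid_threshold
  )
  roc <- purrr::map(c(train = "train", test = "test"), function(sp) {
    s <- scores[scores$split == sp, ]
    dplyr::bind_cols(
      tibble::tibble(split = sp),
      roc_analysis(s$deep_score, s$positive, cutoff)
    )
  })
  roc <- purrr::list_rbind(roc)

  exposure <- exposure_bias_test(scores$error, scores$smartphone_exposure)
  fine_motor <- fine_motor_correlation(scores$error, scores$bsid_fine_motor)
  lp <- levels_played_per_child(
    cohort$sessions, child_ids = cohort$children$child_id
  )
  fc <- floor_ceiling_analysis(
    cohort$children, lp, pct_low = pct_low,
    max_levels = schema_total_levels(cohort$schema)
  )

  structure(
    list(
      agreement = agreement, roc = roc, exposure = exposure,
      fine_motor = fine_motor, floor_ceiling = fc, cutoff = cutoff,
      bsid_threshold = bsid_threshold,
      excluded = attr(predictions, "excluded"), scores = scores
    ),
    class = "deep_evaluation"
  )
}

#' @export
print.deep_evaluation <- function(x, ...) {
  cat("<deep_evaluation>\n")
  cat("  benchmark 25th-percentile threshold:", x$bsid_threshold,
      " | score cutoff:", round(x$cutoff, 2), "\n")
  ag <- x$agreement
  for (i in seq_len(nrow(ag))) {
    cat(sprintf(
      "  %-5s (n=%3d): r = %.3f [%.2f, %.2f]  ICC = %.3f  MAE = %.2f (%.2f)  bias = %+.2f\n",
      ag$split[i], ag$n[i], ag$pearson_r[i], ag$pearson_low[i],
      ag$pearson_high[i], ag$icc[i], ag$mae[i], ag$mae_sd[i], ag$bias[i]
    ))
  }
  rc <- x$roc
  for (i in seq_len(nrow(rc))) {
    cat(sprintf(
      "  %-5s ROC: AUC = %.3f  sens = %.3f  spec = %.3f  acc = %.1f%%\n",
      rc$split[i], rc$auc[i], rc$sensitivity[i], rc$specificity[i],
      100 * rc$accuracy[i]
    ))
  }
  if (length(x$excluded) > 0) {
    cat("  excluded children:", paste(x$excluded, collapse = ", "), "\n")
  }
  invisible(x)
}
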