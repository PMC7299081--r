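#' Run the full analysis pipeline
#'
#' Orchestrates simulate, split, feature assembly, repeated-CV model
#' training, ensembling, prediction and evaluation. A single global seed
#' fans out to per-stage seeds by a fixed counter derivation, so the whole
#' run is reproducible end to end and stages can be rerun independently.
#'
#' @param sim A [sim_config()] for the cohort (ignored if `cohort` given).
#' @param cv A [cv_config()].
#' @param feat A [feature_config()].
#' @param seed Optional global seed; when supplied it overrides the
#'   stage seeds as `sim$seed = seed + 11`, `cv$seed = seed + 23`.
#' @param cohort Optional pre-built `deep_cohort` (skips simulation).
#' @param paperlike If TRUE, data-dependent feature transforms are fitted
#'   on the whole cohort instead of the training rows only, reproducing a
#'   whole-dataset analysis.
#' @param out_dir Optional directory: writes the cohort, the report JSON,
#'   a Bland-Altman point file, a markdown summary, and a manifest.
#' @return A `deep_pipeline` bundle: `cohort`, `split`, `features`,
#'   `cv_results`, `top_models`, `ensemble`, `predictions`, `evaluation`,
#'   `manifest`.
#' @export
run_pipeline <- function(sim = sim_config(), cv = cv_config(),
                         feat = feature_config(), seed = NULL,
                         cohort = NULL, paperlike = FALSE, out_dir = NULL) {
  if (!is.null(seed)) {
    stopifnot(rlang::is_scalar_integerish(seed))
    sim$seed <- as.integer(seed) + 11L
    cv$seed <- as.integer(seed) + 23L
  }
  sim <- validate_sim_config(sim)
  if (is.null(cohort)) cohort <- simulate_cohort(sim)
  split <- split_train_test(cohort, cv)
  fit_ids <- if (paperlike) NULL else split$train_ids
  fm <- assemble_feature_set(cohort, train_ids = fit_ids, config = feat)
  fm_train <- fm_filter(fm, split$train_ids)
  y_train <- cohort$children$bsid_cognitive_raw[
    match(fm_train$data$child_id, cohort$children$child_id)
  ]
  results <- run_repeated_cv(fm_train, y_train, cv)
  top <- rank_and_select(results, cv)
  support <- if (!is.null(cohort$config$support)) {
    range(cohort$config$support)
  } else {
    range(cohort$children$bsid_cognitive_raw)
  }
  ensemble <- build_ensemble(top, fm_train, y_train, cv, support = support)
  predictions <- predict_deep_scores(ensemble, fm)
  # training children are evaluated on their fold-held-out stacked scores;
  # test children on the refit ensemble
  pred_eval <- predictions
  oof_at <- match(pred_eval$child_id, ensemble$train_oof$child_id)
  swap <- which(!is.na(oof_at))
  pred_eval$deep_score[swap] <- ensemble$train_oof$deep_score[oof_at[swap]]
  evaluation <- deep_evaluate(pred_eval, cohort, split$train_ids)
  manifest <- list(
    seed = seed, sim_seed = sim$seed, cv_seed = cv$seed,
    paperlike = paperlike,
    config_hash = rlang::hash(list(sim = unclass(sim), cv = unclass(cv),
                                   feat = unclass(feat))),
    n_children = nrow(cohort$children),
    n_features = nrow(fm$meta),
    composition = feature_report(fm)
  )
  bundle <- structure(
    list(
      cohort = cohort, split = split, features = fm, cv_results = results,
      top_models = top, ensemble = ensemble, predictions = predictions,
      evaluation = evaluation, manifest = manifest
    ),
    class = "deep_pipeline"
  )
  if (!is.null(out_dir)) deep_report(bundle, out_dir)
  bundle
}

#' @export
print.deep_pipeline <- function(x, ...) {
  cat("<deep_pipeline> seed ", format(x$manifest$seed), ", ",
    x$manifest$n_children, " children, ", x$manifest$n_features,
    " features\n",
    sep = ""
  )
  print(x$evaluation)
  invisible(x)
}

report_summary <- function(bundle) {
  ev <- bundle$evaluation
  list(
    manifest = bundle$manifest[c(
      "seed", "sim_seed", "cv_seed", "paperlike", "config_hash",
      "n_children", "n_features"
    )],
    composition = bundle$manifest$composition,
    top_models = bundle$top_models[, c(
      "selector", "learner", "holdout_r", "n_features"
    )],
    selected_features = purrr::map(
      bundle$ensemble$base_models,
      ~ list(model = .x$model, features = .x$features)
    ),
    agreement = ev$agreement,
    roc = ev$roc,
    exposure = ev$exposure,
    fine_motor = ev$fine_motor,
    floor_ceiling = if (nrow(ev$floor_ceiling) > 0) {
      ev$floor_ceiling[, c("group", "n", "n_lt10", "n_not_all")]
    },
    cutoff = ev$cutoff,
    bsid_threshold = ev$bsid_threshold,
    excluded_children = as.list(ev$excluded)
  )
}

#' Write the report bundle for a pipeline run
#'
#' Emits `report.json` (all metrics for train and test, the top-model
#' manifest with selected features, exclusions), `bland_altman.csv` (the
#' per-child agreement points) and `report.md` (a readable summary).
#' Output is byte-identical across reruns of the same configuration.
#'
#' @param bundle A `deep_pipeline`.
#' @param out_dir Output directory, created if absent.
#' @return `out_dir`, invisibly.
#' @export
deep_report <- function(bundle, out_dir) {
  if (is.null(bundle$evaluation)) {
    stop("pipeline bundle has no evaluation stage; cannot report",
      call. = FALSE
    )
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  summary <- report_summary(bundle)
  jsonlite::write_json(
    summary, file.path(out_dir, "report.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null"
  )
  ba <- bland_altman_points(
    bundle$evaluation$scores$deep_score,
    bundle$evaluation$scores$bsid_cognitive_raw
  )
  pts <- ba$points
  pts$child_id <- bundle$evaluation$scores$child_id
  pts$split <- bundle$evaluation$scores$split
  readr::write_csv(pts[, c("child_id", "split", "mean", "diff")],
    file.path(out_dir, "bland_altman.csv")
  )
  ag <- bundle$evaluation$agreement
  rc <- bundle$evaluation$roc
  md <- c(
    "# Pipeline report", "",
    sprintf("- children: %d, features: %d", summary$manifest$n_children,
            summary$manifest$n_features),
    sprintf("- benchmark 25th-percentile threshold: %s, score cutoff: %.2f",
            format(summary$bsid_threshold), summary$cutoff),
    "",
    "| split | n | Pearson r [95% CI] | ICC(2,1) | MAE (SD) | RMSE | bias | AUC | sens | spec |",
    "|---|---|---|---|---|---|---|---|---|---|",
    vapply(seq_len(nrow(ag)), function(i) {
      sprintf(
        "| %s | %d | %.3f [%.2f, %.2f] | %.3f | %.2f (%.2f) | %.2f | %+.2f | %.3f | %.3f | %.3f |",
        ag$split[i], ag$n[i], ag$pearson_r[i], ag$pearson_low[i],
        ag$pearson_high[i], ag$icc[i], ag$mae[i], ag$mae_sd[i], ag$rmse[i],
        ag$bias[i], rc$auc[i], rc$sensitivity[i], rc$specificity[i]
      )
    }, character(1)),
    "",
    "## Top models", "",
    vapply(seq_len(nrow(bundle$top_models)), function(i) {
      sprintf(
        "- %s (CV r = %.3f, %.1f features)", bundle$top_models$model[i],
        bundle$top_models$holdout_r[i], bundle$top_models$n_features[i]
      )
    }, character(1))
  )
  if (length(bundle$evaluation$excluded) > 0) {
    md <- c(md, "", sprintf(
      "Excluded children (missing a contributing game): %s",
      paste(bundle$evaluation$excluded, collapse = ", ")
    ))
  }
  writeLines(md, file.path(out_dir, "report.md"))
  invisible(out_dir)
}
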