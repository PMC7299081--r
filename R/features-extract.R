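# Feature matrices ------------------------------------------------------
#
# A deep_features object is a list with
#   data  : tibble, child_id + one numeric column per feature (NA allowed
#           before imputation)
#   meta  : tibble, per-feature provenance (name, game_scope, level_scope,
#           feature_type, stage, transform, games)
#   mask  : logical matrix children x features, TRUE where the cell was
#           originally missing (unattempted level/game or undefined ratio)
# plus internal state: the per-level stats table the columns were built
# from, the per-level attempted matrix and the per-game attempted matrix.

new_deep_features <- function(data, meta, mask, games_attempted,
                              level_stats = NULL) {
  stopifnot(identical(meta$name, colnames(mask)))
  structure(
    list(data = data, meta = meta, mask = mask,
         games_attempted = games_attempted, level_stats = level_stats),
    class = "deep_features"
  )
}

#' Numeric matrix of a feature object
#'
#' @param fm A `deep_features` object.
#' @return Numeric matrix (children x features) with `child_id` rownames.
#' @export
fm_matrix <- function(fm) {
  x <- as.matrix(fm$data[, -1, drop = FALSE])
  rownames(x) <- fm$data$child_id
  x
}

#' Feature provenance table
#'
#' @param fm A `deep_features` object.
#' @return The `meta` tibble: one row per feature with its name, game scope
#'   (game code, pair code, or `"across"`), level scope (level index,
#'   `"av"`/`"total"`, or empty), feature type, pipeline stage, and any
#'   transform applied.
#' @export
feature_meta <- function(fm) fm$meta

#' @export
print.deep_features <- function(x, ...) {
  counts <- table(factor(
    x$meta$stage,
    levels = c("tablet", "derived", "interaction", "mom", "pca")
  ))
  cat("<deep_features> ", nrow(x$data), " children x ", nrow(x$meta),
    " features (", paste(names(counts), counts, sep = ":", collapse = ", "),
    ")\n",
    sep = ""
  )
  invisible(x)
}

#' @export
as_tibble.deep_features <- function(x, ...) x$data

#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble

# keep only the given children (row subset, preserves fitted provenance)
fm_filter <- function(fm, child_ids) {
  keep <- fm$data$child_id %in% child_ids
  fm$data <- fm$data[keep, , drop = FALSE]
  fm$mask <- fm$mask[keep, , drop = FALSE]
  fm$games_attempted <- fm$games_attempted[keep, , drop = FALSE]
  if (!is.null(fm$level_stats)) {
    fm$level_stats <- fm$level_stats[fm$level_stats$child_id %in% child_ids, ]
  }
  fm
}

# resolve fit rows: integer indices into fm rows; NULL means all rows
fit_row_idx <- function(fm, fit_ids = NULL) {
  if (is.null(fit_ids)) seq_len(nrow(fm$data))
  else which(fm$data$child_id %in% fit_ids)
}

# Per-level stats --------------------------------------------------------

# one row per child x battery level, arranged by (game, level, child) so
# each (game, level) slice is contiguous
build_level_stats <- function(sessions, schema, child_ids) {
  grid <- schema_level_grid(schema)
  grid$game_id <- factor(grid$game_id, levels = schema$game_id)
  full <- tidyr::crossing(child_id = child_ids, grid)
  full$game_id <- factor(full$game_id, levels = schema$game_id)

  base <- sessions[, c("child_id", "game_id", "level", "attempted", "completed")]
  ev <- tidyr::unnest(
    sessions[, c("child_id", "game_id", "level", "events")], "events"
  )
  if (nrow(ev) > 0) {
    ev <- dplyr::left_join(
      ev, schema[, c("game_id", "advance_threshold")], by = "game_id"
    )
    ev_stats <- dplyr::summarize(
      dplyr::group_by(ev, .data$child_id, .data$game_id, .data$level),
      n_tap = sum(.data$gesture == "tap"),
      n_correct_tap = sum(.data$gesture == "tap" & .data$outcome == "correct"),
      n_incorrect_tap = sum(.data$gesture == "tap" & .data$outcome == "incorrect"),
      n_drag = sum(.data$gesture == "drag"),
      n_correct_drag = sum(.data$gesture == "drag" & .data$outcome == "correct"),
      n_incorrect_drag = sum(.data$gesture == "drag" & .data$outcome == "incorrect"),
      n_bg = sum(.data$outcome == "background"),
      n_events = dplyr::n(),
      n_correct = sum(.data$outcome == "correct"),
      n_incorrect = sum(.data$outcome == "incorrect"),
      first_ms = min(.data$t_ms),
      last_ms = max(.data$t_ms),
      latency_ms = .data$t_ms[.data$outcome == "correct"][1],
      completion_s = {
        tc <- .data$t_ms[.data$outcome == "correct"]
        thr <- .data$advance_threshold[1]
        if (length(tc) >= thr) tc[thr] / 1000 else NA_real_
      },
      .groups = "drop"
    )
  } else {
    ev_stats <- tibble::tibble(
      child_id = character(), game_id = factor(character(), levels = schema$game_id),
      level = integer(), n_tap = integer(), n_correct_tap = integer(),
      n_incorrect_tap = integer(), n_drag = integer(), n_correct_drag = integer(),
      n_incorrect_drag = integer(), n_bg = integer(), n_events = integer(),
      n_correct = integer(), n_incorrect = integer(), first_ms = numeric(),
      last_ms = numeric(), latency_ms = numeric(), completion_s = numeric()
    )
  }
  base$game_id <- factor(base$game_id, levels = schema$game_id)
  ev_stats$game_id <- factor(ev_stats$game_id, levels = schema$game_id)

  stats <- dplyr::left_join(full, base, by = c("child_id", "game_id", "level"))
  stats$attempted[is.na(stats$attempted)] <- FALSE
  stats$completed[is.na(stats$completed)] <- FALSE
  stats <- dplyr::left_join(stats, ev_stats, by = c("child_id", "game_id", "level"))

  count_cols <- c(
    "n_tap", "n_correct_tap", "n_incorrect_tap", "n_drag", "n_correct_drag",
    "n_incorrect_drag", "n_bg", "n_events", "n_correct", "n_incorrect"
  )
  for (cc in count_cols) {
    # attempted level with no events has true zero counts; unattempted is NA
    stats[[cc]] <- ifelse(stats$attempted & is.na(stats[[cc]]), 0L, stats[[cc]])
    stats[[cc]] <- ifelse(stats$attempted, stats[[cc]], NA_integer_)
  }
  # completion time is defined (= timer) for attempted-but-uncompleted levels
  stats$completion_s <- ifelse(
    stats$attempted & is.na(stats$completion_s),
    stats$level_timer_s, stats$completion_s
  )
  stats$completion_s <- ifelse(stats$attempted, stats$completion_s, NA_real_)
  stats$playtime_s <- (stats$last_ms - stats$first_ms) / 1000
  dplyr::arrange(stats, .data$game_id, .data$level, .data$child_id)
}

games_attempted_matrix <- function(level_stats, schema, child_ids) {
  by_game <- dplyr::summarize(
    dplyr::group_by(level_stats, .data$child_id, .data$game_id),
    any_att = any(.data$attempted), .groups = "drop"
  )
  wide <- tidyr::pivot_wider(
    by_game, names_from = "game_id", values_from = "any_att"
  )
  wide <- wide[match(child_ids, wide$child_id), ]
  m <- as.matrix(wide[, schema$game_id])
  rownames(m) <- child_ids
  m
}

# Column plan and assembly ----------------------------------------------

LEVEL_DERIVED_TYPES <- c(
  "accuracy_cbyi", "accuracy_cbyt", "correctrate", "playtime",
  "completion_time", "activity"
)

# per-level stat -> feature name/type, conditional on the game's gesture
level_stat_plan <- function(gesture, stage) {
  tap <- tibble::tibble(
    stat = c("n_correct_tap", "n_incorrect_tap", "n_tap"),
    suffix = c("correctclicks", "incorrectclicks", "totalclicks"),
    feature_type = "count"
  )
  drag <- tibble::tibble(
    stat = c("n_correct_drag", "n_incorrect_drag", "n_drag"),
    suffix = c("correctdrags", "incorrectdrag", "totaldrags"),
    feature_type = "count"
  )
  common <- tibble::tibble(
    stat = c("n_bg", "latency_ms", "first_ms", "last_ms"),
    suffix = c("background", "latency", "firstevent", "lastevent"),
    feature_type = c("count", "latency", "timestamp", "timestamp")
  )
  plan <- switch(gesture,
    tap = dplyr::bind_rows(tap, common),
    drag = dplyr::bind_rows(drag, common),
    mixed = dplyr::bind_rows(tap, drag, common)
  )
  if (stage == "derived") {
    plan <- tibble::tibble(
      stat = LEVEL_DERIVED_TYPES, suffix = LEVEL_DERIVED_TYPES,
      feature_type = LEVEL_DERIVED_TYPES
    )
  }
  plan
}

# add per-level derived values (with NA where undefined) + missingness flags
add_level_derived <- function(stats, imputed) {
  st <- stats
  denom_ci <- st$n_correct + st$n_incorrect
  st$accuracy_cbyi <- ifelse(denom_ci > 0, st$n_correct / denom_ci, NA_real_)
  st$accuracy_cbyt <- ifelse(st$n_events > 0, st$n_correct / st$n_events, NA_real_)
  st$correctrate <- ifelse(
    !is.na(st$playtime_s) & st$playtime_s > 0,
    st$n_correct / st$playtime_s, NA_real_
  )
  st$activity <- ifelse(
    !is.na(st$playtime_s) & st$playtime_s > 0,
    st$n_events / st$playtime_s, NA_real_
  )
  st$playtime <- ifelse(!is.na(st$n_events) & st$n_events > 0,
    st$playtime_s, NA_real_
  )
  st$completion_time <- st$completion_s

  # originally-missing flags (recorded before any imputation)
  st$miss_count <- !st$attempted
  st$miss_latency <- !st$attempted | is.na(st$latency_ms)
  st$miss_timestamp <- !st$attempted | is.na(st$first_ms)
  st$miss_accuracy_cbyi <- !st$attempted | is.na(st$accuracy_cbyi)
  st$miss_accuracy_cbyt <- !st$attempted | is.na(st$accuracy_cbyt)
  st$miss_correctrate <- !st$attempted | is.na(st$correctrate)
  st$miss_activity <- !st$attempted | is.na(st$activity)
  st$miss_playtime <- !st$attempted | is.na(st$playtime)
  st$miss_completion_time <- !st$attempted

  if (imputed) {
    timer_ms <- st$level_timer_s * 1000
    for (cc in c(
      "n_tap", "n_correct_tap", "n_incorrect_tap", "n_drag", "n_correct_drag",
      "n_incorrect_drag", "n_bg", "n_events", "n_correct", "n_incorrect"
    )) {
      st[[cc]][is.na(st[[cc]])] <- 0L
    }
    st$latency_ms <- ifelse(is.na(st$latency_ms), timer_ms, st$latency_ms)
    st$first_ms <- ifelse(is.na(st$first_ms), timer_ms, st$first_ms)
    st$last_ms <- ifelse(is.na(st$last_ms), timer_ms, st$last_ms)
    st$completion_time <- ifelse(
      is.na(st$completion_time), st$level_timer_s, st$completion_time
    )
    for (cc in c("accuracy_cbyi", "accuracy_cbyt", "correctrate", "activity",
                 "playtime")) {
      st[[cc]][is.na(st[[cc]])] <- 0
    }
  }
  st
}

# per-game / pair / across-games aggregate block
build_aggregates <- function(st, schema, child_ids, imputed) {
  na_rm <- !imputed
  mean_ <- function(x) {
    m <- mean(x, na.rm = na_rm)
    if (is.nan(m)) NA_real_ else m
  }
  sum_ <- function(x) if (na_rm && all(is.na(x))) NA_real_ else sum(x, na.rm = na_rm)
  acc_ <- function(num, den) {
    n <- sum_(num); d <- sum_(den)
    if (is.na(d)) return(NA_real_)
    if (d == 0) return(if (imputed) 0 else NA_real_)
    n / d
  }
  per_game <- dplyr::summarize(
    dplyr::group_by(st, .data$child_id, .data$game_id),
    levels_played = sum(.data$attempted),
    av_accuracy_cbyi = mean_(.data$accuracy_cbyi),
    av_accuracy_cbyt = mean_(.data$accuracy_cbyt),
    av_correctrate = mean_(.data$correctrate),
    av_latency = mean_(.data$latency_ms),
    av_playtime = mean_(.data$playtime),
    av_activity = mean_(.data$activity),
    av_completion_time = mean_(.data$completion_time),
    correctclicks = sum_(.data$n_correct_tap),
    totalclicks = sum_(.data$n_tap),
    total_incorrectclick = sum_(.data$n_incorrect_tap),
    correctdrags = sum_(.data$n_correct_drag),
    totaldrags = sum_(.data$n_drag),
    total_incorrectdrag = sum_(.data$n_incorrect_drag),
    background = sum_(.data$n_bg),
    total_playtime = sum_(.data$playtime),
    total_completion_time = sum_(.data$completion_time),
    total_accuracy_cbyi = acc_(.data$n_correct, .data$n_correct + .data$n_incorrect),
    total_accuracy_cbyt = acc_(.data$n_correct, .data$n_events),
    .groups = "drop"
  )
  per_game <- dplyr::arrange(per_game, .data$game_id, .data$child_id)
  per_game
}

agg_column_plan <- function(schema) {
  per_game <- purrr::map(seq_len(nrow(schema)), function(i) {
    g <- schema$game_id[i]
    gesture <- schema$gesture[i]
    avs <- c(
      "av_accuracy_cbyi", "av_accuracy_cbyt", "av_correctrate", "av_latency",
      "av_playtime", "av_activity", "av_completion_time"
    )
    counts <- switch(gesture,
      tap = c("correctclicks", "totalclicks", "total_incorrectclick"),
      drag = c("correctdrags", "totaldrags", "total_incorrectdrag"),
      mixed = c(
        "correctclicks", "totalclicks", "total_incorrectclick",
        "correctdrags", "totaldrags", "total_incorrectdrag"
      )
    )
    cols <- c(
      "levels_played", avs, counts, "background", "total_playtime",
      "total_completion_time", "total_accuracy_cbyi", "total_accuracy_cbyt"
    )
    type <- dplyr::case_when(
      cols == "levels_played" ~ "levels_played",
      cols == "av_latency" ~ "latency",
      cols %in% c("total_accuracy_cbyi", "av_accuracy_cbyi") ~ "accuracy_cbyi",
      cols %in% c("total_accuracy_cbyt", "av_accuracy_cbyt") ~ "accuracy_cbyt",
      cols %in% c("av_correctrate") ~ "correctrate",
      cols %in% c("av_playtime", "total_playtime") ~ "playtime",
      cols %in% c("av_completion_time", "total_completion_time") ~ "completion_time",
      cols == "av_activity" ~ "activity",
      .default = "count"
    )
    tibble::tibble(
      game_scope = g, agg = cols, name = paste0(g, "_", cols),
      feature_type = type,
      level_scope = ifelse(grepl("^av_", cols), "av",
        ifelse(cols == "levels_played", "", "total")
      )
    )
  })
  purrr::list_rbind(per_game)
}

#' Extract raw ("from the tablet") features from event logs
#'
#' Computes, for every child and every level of the battery, event counts by
#' outcome and gesture plus first/last event timestamps and the latency of
#' the first correct response. Cells for unattempted levels, and timestamp
#' cells for levels with no (correct) events, are NA and flagged in the
#' missingness mask.
#'
#' @param sessions Validated session tibble.
#' @param schema Game schema.
#' @param child_ids Children to include (defaults to those in `sessions`);
#'   children without sessions get fully masked rows.
#' @return A `deep_features` object of stage-`tablet` columns.
#' @export
extract_raw_features <- function(sessions, schema = deep_schema(),
                                 child_ids = NULL) {
  if (is.null(child_ids)) child_ids <- sort(unique(sessions$child_id))
  stats <- build_level_stats(sessions, schema, child_ids)
  build_feature_object(stats, schema, child_ids,
    stages = "tablet", imputed = FALSE
  )
}

#' Add derived features to a raw feature matrix
#'
#' Computes the derived feature registry per level (accuracy by included
#' events, accuracy by all events, correct responses per second, playtime,
#' completion time, activity), per-game aggregates (levels played, `av_*`
#' means over levels, `total_*` sums and pooled accuracies), the pair
#' aggregate over the two drag games (`msjig_*`), and across-game sums
#' (`sum_all_levels_played`, `sum_completion_time`, `sum_total_playtime`,
#' `sum_total_accuracy_cbyt`, `sum_background`). Cells whose definition
#' divides by zero are NA and flagged for imputation.
#'
#' @param fm A `deep_features` from [extract_raw_features()].
#' @param schema Game schema.
#' @return A `deep_features` with `tablet` + `derived` stages.
#' @export
derive_features <- function(fm, schema = deep_schema()) {
  build_feature_object(
    fm$level_stats, schema, fm$data$child_id,
    stages = c("tablet", "derived"), imputed = FALSE
  )
}

#' Impute missing feature cells
#'
#' Fills every originally-missing cell with its registry value: accuracies,
#' rates, activity, playtime and counts get 0; latencies and timestamps get
#' the level timer (in ms); completion times get the level timer (in s).
#' Game-level and across-game aggregates are then recomputed from the filled
#' per-level values, so e.g. the across-game completion-time sum counts
#' every missed level at the full timer. The missingness mask is preserved.
#'
#' A fully played child's row is unchanged by imputation.
#'
#' @param fm A `deep_features` from [derive_features()].
#' @param schema Game schema.
#' @return A `deep_features` with no NA cells.
#' @export
impute_missing <- function(fm, schema = deep_schema()) {
  out <- build_feature_object(
    fm$level_stats, schema, fm$data$child_id,
    stages = c("tablet", "derived"), imputed = TRUE
  )
  if (anyNA(as.matrix(out$data[, -1]))) {
    bad <- names(out$data[, -1])[colSums(is.na(out$data[, -1])) > 0]
    stop("no imputation rule produced a value for: ",
      paste(utils::head(bad, 5), collapse = ", "),
      call. = FALSE
    )
  }
  out
}

# shared builder for raw/derived/imputed feature objects
build_feature_object <- function(level_stats, schema, child_ids, stages,
                                 imputed) {
  n <- length(child_ids)
  st <- add_level_derived(level_stats, imputed = imputed)
  # (game, level, child) slices are contiguous; map to child order
  st_child <- match(st$child_id, child_ids)
  grid <- schema_level_grid(schema)

  cols <- list()
  meta <- list()
  masks <- list()
  slice_of <- function(stat, block) {
    v <- st[[stat]][block]
    v[order(st_child[block])]
  }
  for (b in seq_len(nrow(grid))) {
    block <- ((b - 1) * n + 1):(b * n)
    g <- grid$game_id[b]
    k <- grid$level[b]
    for (stage in intersect(stages, c("tablet", "derived"))) {
      plan <- level_stat_plan(grid$gesture[b], stage)
      for (j in seq_len(nrow(plan))) {
        nm <- paste0(g, "_l", k, "_", plan$suffix[j])
        cols[[nm]] <- as.numeric(slice_of(plan$stat[j], block))
        masks[[nm]] <- slice_of(paste0("miss_", plan$feature_type[j]), block)
        meta[[nm]] <- tibble::tibble(
          name = nm, game_scope = g, level_scope = as.character(k),
          feature_type = plan$feature_type[j],
          stage = stage, transform = "none", games = g
        )
      }
    }
  }

  games_att <- games_attempted_matrix(level_stats, schema, child_ids)

  if ("derived" %in% stages) {
    agg <- build_aggregates(st, schema, child_ids, imputed = imputed)
    plan <- agg_column_plan(schema)
    agg_child <- match(agg$child_id, child_ids)
    for (j in seq_len(nrow(plan))) {
      block <- which(agg$game_id == plan$game_scope[j])
      v <- agg[[plan$agg[j]]][block]
      v <- v[order(agg_child[block])]
      nm <- plan$name[j]
      cols[[nm]] <- as.numeric(v)
      masks[[nm]] <- !games_att[, plan$game_scope[j]]
      meta[[nm]] <- tibble::tibble(
        name = nm, game_scope = plan$game_scope[j],
        level_scope = plan$level_scope[j],
        feature_type = plan$feature_type[j],
        stage = "derived", transform = "none", games = plan$game_scope[j]
      )
    }
    # pair aggregate over the two drag games
    pair_mask <- !(games_att[, "ms"] & games_att[, "jig"])
    pair_defs <- list(
      msjig_correctdrags = c("ms_correctdrags", "jig_correctdrags"),
      msjig_totaldrags = c("ms_totaldrags", "jig_totaldrags"),
      msjig_total_incorrectdrag = c("ms_total_incorrectdrag", "jig_total_incorrectdrag"),
      msjig_total_playtime = c("ms_total_playtime", "jig_total_playtime"),
      msjig_total_completion_time = c("ms_total_completion_time", "jig_total_completion_time")
    )
    pair_types <- c("count", "count", "count", "playtime", "completion_time")
    for (j in seq_along(pair_defs)) {
      nm <- names(pair_defs)[j]
      parts <- pair_defs[[j]]
      v <- cols[[parts[1]]] + cols[[parts[2]]]
      cols[[nm]] <- v
      masks[[nm]] <- pair_mask
      meta[[nm]] <- tibble::tibble(
        name = nm, game_scope = "msjig", level_scope = "total",
        feature_type = pair_types[j], stage = "derived", transform = "none",
        games = "ms,jig"
      )
    }
    # across-games sums
    gsum <- function(suffix) {
      Reduce(`+`, purrr::map(schema$game_id, ~ cols[[paste0(.x, "_", suffix)]]))
    }
    across_defs <- tibble::tibble(
      name = c(
        "sum_all_levels_played", "sum_completion_time", "sum_total_playtime",
        "sum_total_accuracy_cbyt", "sum_background"
      ),
      suffix = c(
        "levels_played", "total_completion_time", "total_playtime",
        "total_accuracy_cbyt", "background"
      ),
      feature_type = c(
        "levels_played", "completion_time", "playtime", "accuracy_cbyt",
        "count"
      )
    )
    all_att <- apply(games_att, 1, all)
    for (j in seq_len(nrow(across_defs))) {
      nm <- across_defs$name[j]
      cols[[nm]] <- gsum(across_defs$suffix[j])
      # a levels-played count is defined for every child; the other sums
      # involve a partially imputed game whenever one was unattempted
      masks[[nm]] <- if (nm == "sum_all_levels_played") rep(FALSE, n) else !all_att
      meta[[nm]] <- tibble::tibble(
        name = nm, game_scope = "across", level_scope = "",
        feature_type = across_defs$feature_type[j], stage = "derived",
        transform = "none", games = ""
      )
    }
  }

  data <- tibble::as_tibble(c(list(child_id = child_ids), cols))
  mask <- do.call(cbind, masks)
  colnames(mask) <- names(cols)
  rownames(mask) <- child_ids
  new_deep_features(
    data = data,
    meta = purrr::list_rbind(meta),
    mask = mask,
    games_attempted = games_att,
    level_stats = level_stats
  )
}

#' Levels played per child
#'
#' @param sessions Session tibble.
#' @param child_ids Optional ids to include (children absent from
#'   `sessions` get 0).
#' @return Tibble `child_id`, `levels_played` (count of attempted levels,
#'   at most the battery total of 40 under the default schema).
#' @export
levels_played_per_child <- function(sessions, child_ids = NULL) {
  counts <- dplyr::count(
    dplyr::filter(sessions, .data$attempted),
    .data$child_id,
    name = "levels_played"
  )
  if (!is.null(child_ids)) {
    counts <- dplyr::left_join(
      tibble::tibble(child_id = child_ids), counts, by = "child_id"
    )
    counts$levels_played[is.na(counts$levels_played)] <- 0L
  }
  counts
}
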