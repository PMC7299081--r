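# Data-dependent feature transforms. Every function here that estimates
# something from the data (skewness, correlations, the interaction subset,
# mas-o-menos weights, PCA loadings, scaling constants) fits on `fit_ids`
# (the training children) and applies to all rows; `fit_ids = NULL` fits on
# everything, reproducing a whole-dataset ("paper-like") analysis.

#' Adjusted Fisher--Pearson sample skewness
#'
#' @param x Numeric vector (NA removed).
#' @return `G1 = g1 * sqrt(n(n-1)) / (n-2)` where `g1 = m3 / m2^(3/2)`;
#'   NA for fewer than 3 values or zero variance.
#' @export
sample_skewness <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 3) return(NA_real_)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) return(NA_real_)
  g1 <- mean((x - m)^3) / m2^1.5
  g1 * sqrt(n * (n - 1)) / (n - 2)
}

#' Symmetrize skewed feature columns
#'
#' Columns with skewness above `threshold` are square-root transformed
#' (after shifting so the minimum is non-negative); columns with skewness
#' below `-threshold` are squared. Transformed columns are renamed with a
#' `_sqrt` / `_sq` suffix and the transform is recorded in the feature
#' metadata. Applied once, never iteratively.
#'
#' @param fm An imputed `deep_features`.
#' @param threshold Absolute skewness above which to transform (default 1).
#' @param fit_ids Children whose rows the skewness (and any sqrt shift) is
#'   estimated on; NULL for all.
#' @return List with `features` (the transformed object) and `log`
#'   (tibble: `name`, `skewness`, `transform`, `new_name`).
#' @export
skew_transform <- function(fm, threshold = 1, fit_ids = NULL) {
  idx <- fit_row_idx(fm, fit_ids)
  nms <- fm$meta$name
  log <- tibble::tibble(
    name = nms, skewness = NA_real_, transform = "none", new_name = nms
  )
  for (j in seq_along(nms)) {
    x_fit <- fm$data[[nms[j]]][idx]
    sk <- sample_skewness(x_fit)
    log$skewness[j] <- sk
    if (is.na(sk)) next
    if (sk > threshold) {
      shift <- min(x_fit)
      fm$data[[nms[j]]] <- sqrt(pmax(fm$data[[nms[j]]] - min(shift, 0), 0))
      log$transform[j] <- "sqrt"
    } else if (sk < -threshold) {
      fm$data[[nms[j]]] <- fm$data[[nms[j]]]^2
      log$transform[j] <- "square"
    }
  }
  suffix <- c(none = "", sqrt = "_sqrt", square = "_sq")
  log$new_name <- paste0(log$name, suffix[log$transform])
  names(fm$data) <- c("child_id", log$new_name)
  colnames(fm$mask) <- log$new_name
  fm$meta$name <- log$new_name
  fm$meta$transform <- log$transform
  list(features = fm, log = log)
}

#' Drop highly correlated features
#'
#' Greedy left-to-right scan in column order: a column is dropped when its
#' absolute Pearson correlation with any *retained* earlier column exceeds
#' `r_max`, so the surviving set has no pair above the cap. Zero-variance
#' columns correlate with nothing and are retained with a warning.
#'
#' @param fm A `deep_features`.
#' @param r_max Correlation cap (default 0.9).
#' @param fit_ids Children correlations are estimated on; NULL for all.
#' @return The pruned `deep_features`.
#' @export
prune_correlated <- function(fm, r_max = 0.9, fit_ids = NULL) {
  idx <- fit_row_idx(fm, fit_ids)
  x <- fm_matrix(fm)[idx, , drop = FALSE]
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    warning(
      sum(sds == 0), " zero-variance feature(s) retained unexamined: ",
      paste(utils::head(colnames(x)[sds == 0], 3), collapse = ", ")
    )
  }
  cm <- suppressWarnings(abs(stats::cor(x)))
  cm[is.na(cm)] <- 0
  p <- ncol(x)
  keep <- logical(p)
  for (j in seq_len(p)) {
    keep[j] <- !any(cm[j, which(keep[seq_len(j - 1)])] > r_max)
  }
  fm_keep_columns(fm, fm$meta$name[keep])
}

fm_keep_columns <- function(fm, names_keep) {
  fm$data <- fm$data[, c("child_id", names_keep)]
  fm$mask <- fm$mask[, names_keep, drop = FALSE]
  fm$meta <- fm$meta[match(names_keep, fm$meta$name), ]
  fm
}

fm_append <- function(fm, values, meta, mask = NULL) {
  stopifnot(nrow(meta) == ncol(values))
  if (is.null(mask)) {
    mask <- matrix(FALSE, nrow(fm$data), ncol(values))
  }
  colnames(values) <- meta$name
  colnames(mask) <- meta$name
  for (j in seq_len(ncol(values))) {
    fm$data[[meta$name[j]]] <- unname(values[, j])
  }
  fm$mask <- cbind(fm$mask, mask)
  fm$meta <- dplyr::bind_rows(fm$meta, meta)
  fm
}

#' Choose the interaction subset
#'
#' Picks the `n` features most correlated (in absolute value, on the fit
#' rows) with the outcome, among the tablet/derived stages. Ties break by
#' name for determinism.
#'
#' @param fm A `deep_features`.
#' @param y Outcome for the fit rows (aligned to `fit_ids`, or to all rows).
#' @param n Subset size (default 20).
#' @param fit_ids Training children; NULL for all.
#' @return Character vector of feature names.
#' @export
choose_interaction_subset <- function(fm, y, n = 20, fit_ids = NULL) {
  idx <- fit_row_idx(fm, fit_ids)
  x <- fm_matrix(fm)[idx, , drop = FALSE]
  r <- suppressWarnings(abs(as.vector(stats::cor(x, y))))
  r[is.na(r)] <- 0
  ord <- order(-r, colnames(x))
  colnames(x)[ord][seq_len(min(n, ncol(x)))]
}

#' Build two-way interaction features
#'
#' Forms all pairwise products and both-direction ratios of the subset
#' features. A candidate cell is "null" when either parent was originally
#' missing, or (for ratios) the denominator is zero; null ratio cells are
#' filled with 0 and masked. Candidates with at least `null_max` null cells
#' on the fit rows, or with |r| > `r_max` against any existing retained
#' feature or earlier-accepted candidate, are dropped. Survivors are
#' appended with stage `interaction` and names `a_times_b` / `a_div_by_b`.
#'
#' @param fm An imputed `deep_features`.
#' @param subset Character vector of parent feature names (must exist).
#' @param r_max Correlation cap against existing features (default 0.9).
#' @param null_max Maximum allowed null fraction (default 0.15).
#' @param fit_ids Training children; NULL for all.
#' @return The `deep_features` with surviving interactions appended.
#' @export
build_interactions <- function(fm, subset, r_max = 0.9, null_max = 0.15,
                               fit_ids = NULL) {
  missing_parents <- setdiff(subset, fm$meta$name)
  if (length(missing_parents) > 0) {
    stop("interaction subset names absent from the feature set: ",
      paste(missing_parents, collapse = ", "),
      call. = FALSE
    )
  }
  idx <- fit_row_idx(fm, fit_ids)
  x <- fm_matrix(fm)
  existing <- x[idx, , drop = FALSE]
  games_of <- stats::setNames(fm$meta$games, fm$meta$name)

  union_games <- function(a, b) {
    g <- union(
      strsplit(games_of[[a]], ",")[[1]],
      strsplit(games_of[[b]], ",")[[1]]
    )
    paste(sort(g[nzchar(g)]), collapse = ",")
  }
  accepted_vals <- list()
  accepted_meta <- list()
  accepted_mask <- list()
  ok <- function(v, msk) {
    if (mean(msk[idx]) >= null_max) return(FALSE)
    if (stats::sd(v[idx]) == 0) return(FALSE)
    r1 <- suppressWarnings(abs(as.vector(stats::cor(existing, v[idx]))))
    if (any(r1 > r_max, na.rm = TRUE)) return(FALSE)
    if (length(accepted_vals) > 0) {
      prev <- vapply(
        accepted_vals,
        function(a) suppressWarnings(abs(stats::cor(a[idx], v[idx]))),
        numeric(1)
      )
      if (any(prev > r_max, na.rm = TRUE)) return(FALSE)
    }
    TRUE
  }
  add <- function(nm, v, msk, a, b) {
    accepted_vals[[nm]] <<- v
    accepted_mask[[nm]] <<- msk
    accepted_meta[[nm]] <<- tibble::tibble(
      name = nm, game_scope = union_games(a, b), level_scope = "",
      feature_type = "interaction", stage = "interaction",
      transform = "none", games = union_games(a, b)
    )
  }
  for (i in seq_along(subset)) {
    for (j in seq_along(subset)) {
      if (j <= i) next
      a <- subset[i]
      b <- subset[j]
      mab <- fm$mask[, a] | fm$mask[, b]
      prod_v <- x[, a] * x[, b]
      nm <- paste0(a, "_times_", b)
      if (ok(prod_v, mab)) add(nm, prod_v, mab, a, b)
      for (pair in list(c(a, b), c(b, a))) {
        den <- x[, pair[2]]
        msk <- mab | den == 0
        v <- ifelse(den == 0, 0, x[, pair[1]] / den)
        nm <- paste0(pair[1], "_div_by_", pair[2])
        if (ok(v, msk)) add(nm, v, msk, pair[1], pair[2])
      }
    }
  }
  if (length(accepted_vals) == 0) return(fm)
  fm_append(
    fm,
    do.call(cbind, accepted_vals),
    purrr::list_rbind(accepted_meta),
    do.call(cbind, accepted_mask)
  )
}

#' Append the mas-o-menos composite
#'
#' Standardizes every tablet/derived/interaction column with training
#' means/SDs, weights each by the sign of its training correlation with the
#' outcome, and averages: a parsimonious composite that needs no
#' coefficient estimation beyond the signs. Zero-variance columns get
#' weight 0 and are excluded from the average.
#'
#' @param fm An imputed `deep_features`.
#' @param y Outcome aligned to the fit rows.
#' @param fit_ids Training children; NULL for all.
#' @return The `deep_features` with a `mom` column (stage `mom`) appended;
#'   the fitted weights are stored in `attr(, "mom_fit")`.
#' @export
mas_o_menos <- function(fm, y, fit_ids = NULL) {
  idx <- fit_row_idx(fm, fit_ids)
  use <- fm$meta$name[fm$meta$stage %in% c("tablet", "derived", "interaction")]
  x <- fm_matrix(fm)[, use, drop = FALSE]
  mu <- colMeans(x[idx, , drop = FALSE])
  sd_ <- apply(x[idx, , drop = FALSE], 2, stats::sd)
  w <- sign(suppressWarnings(as.vector(stats::cor(x[idx, , drop = FALSE], y))))
  w[is.na(w) | sd_ == 0] <- 0
  active <- which(w != 0)
  z <- sweep(
    sweep(x[, active, drop = FALSE], 2, mu[active]),
    2, sd_[active], "/"
  )
  mom <- as.vector(z %*% w[active]) / length(active)
  fit <- tibble::tibble(name = use, weight = w, mean = mu, sd = sd_)
  fm <- fm_append(
    fm,
    matrix(mom, ncol = 1),
    tibble::tibble(
      name = "mom", game_scope = "across", level_scope = "",
      feature_type = "mom", stage = "mom", transform = "none", games = ""
    )
  )
  attr(fm, "mom_fit") <- fit
  fm
}

#' Append principal-component features
#'
#' Standardizes the tablet/derived/interaction/mom columns with training
#' means/SDs, fits a PCA on the training rows, and appends the scores of
#' the smallest number of leading components whose cumulative explained
#' variance reaches `var_target`. Components are capped at the matrix rank
#' (with a warning if the cap binds).
#'
#' @param fm An imputed `deep_features`.
#' @param var_target Cumulative explained-variance target (default 0.70).
#' @param fit_ids Training children; NULL for all.
#' @return The `deep_features` with `pc1..pcm` columns (stage `pca`)
#'   appended; loadings are stored in `attr(, "pca_fit")`.
#' @export
pca_features <- function(fm, var_target = 0.70, fit_ids = NULL) {
  idx <- fit_row_idx(fm, fit_ids)
  use <- fm$meta$name[
    fm$meta$stage %in% c("tablet", "derived", "interaction", "mom")
  ]
  x <- fm_matrix(fm)[, use, drop = FALSE]
  mu <- colMeans(x[idx, , drop = FALSE])
  sd_ <- apply(x[idx, , drop = FALSE], 2, stats::sd)
  keep <- sd_ > 0
  z <- sweep(sweep(x[, keep, drop = FALSE], 2, mu[keep]), 2, sd_[keep], "/")
  pc <- stats::prcomp(z[idx, , drop = FALSE], center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  cum <- cumsum(ev) / sum(ev)
  m <- which(cum >= var_target)[1]
  if (is.na(m)) {
    m <- length(ev)
    warning("rank-deficient matrix: components capped at rank ", m)
  }
  scores <- sweep(z, 2, pc$center) %*% pc$rotation[, seq_len(m), drop = FALSE]
  meta <- tibble::tibble(
    name = paste0("pc", seq_len(m)), game_scope = "across", level_scope = "",
    feature_type = "pca", stage = "pca", transform = "none", games = ""
  )
  fm <- fm_append(fm, scores, meta)
  attr(fm, "pca_fit") <- list(
    columns = names(mu)[keep], mean = mu[keep], sd = sd_[keep],
    center = pc$center, rotation = pc$rotation[, seq_len(m), drop = FALSE],
    explained = cum[m], n_components = m
  )
  fm
}

#' Standardize all feature columns
#'
#' @param fm A `deep_features`.
#' @param fit_ids Training children whose means/SDs are used; NULL for all.
#' @return The scaled `deep_features` (zero-variance columns are centered
#'   only).
#' @export
scale_features <- function(fm, fit_ids = NULL) {
  idx <- fit_row_idx(fm, fit_ids)
  x <- fm_matrix(fm)
  mu <- colMeans(x[idx, , drop = FALSE])
  sd_ <- apply(x[idx, , drop = FALSE], 2, stats::sd)
  sd_[sd_ == 0] <- 1
  z <- sweep(sweep(x, 2, mu), 2, sd_, "/")
  for (j in seq_len(ncol(z))) fm$data[[colnames(z)[j]]] <- z[, j]
  attr(fm, "scale_fit") <- tibble::tibble(
    name = colnames(z), mean = mu, sd = sd_
  )
  fm
}

#' Feature-assembly configuration
#'
#' @param r_max Correlation cap for pruning and interaction filtering.
#' @param skew_threshold Absolute skewness triggering a transform.
#' @param interaction_subset Explicit parent names, or NULL to pick the
#'   `interaction_subset_size` features most correlated with the outcome.
#' @param interaction_subset_size Size of the interaction subset.
#' @param null_max Null-fraction cap for interaction candidates.
#' @param pca_var_target Explained-variance target for the PCA block.
#' @return A `feature_config` list.
#' @export
feature_config <- function(r_max = 0.9, skew_threshold = 1,
                           interaction_subset = NULL,
                           interaction_subset_size = 20, null_max = 0.15,
                           pca_var_target = 0.70) {
  structure(
    list(
      r_max = r_max, skew_threshold = skew_threshold,
      interaction_subset = interaction_subset,
      interaction_subset_size = interaction_subset_size,
      null_max = null_max, pca_var_target = pca_var_target
    ),
    class = "feature_config"
  )
}

#' Assemble the full feature set for a cohort
#'
#' Runs extract, derive, impute, skew transform, correlation pruning,
#' interaction construction, mas-o-menos and PCA, then scales everything.
#' All data-dependent steps fit on `train_ids` and apply to every child;
#' with `train_ids = NULL` they fit on the whole cohort (the whole-dataset
#' "paper-like" mode).
#'
#' @param cohort A `deep_cohort` (or list with `children`, `sessions`,
#'   `schema`).
#' @param train_ids Training child ids, or NULL.
#' @param config A [feature_config()].
#' @return A scaled `deep_features`; `attr(, "composition")` reports the
#'   per-stage column counts and `attr(, "interaction_subset")` the parent
#'   features used.
#' @export
assemble_feature_set <- function(cohort, train_ids = NULL,
                                 config = feature_config()) {
  schema <- cohort$schema
  children <- cohort$children
  y_ids <- if (is.null(train_ids)) children$child_id else train_ids
  y <- children$bsid_cognitive_raw[match(sort(y_ids), children$child_id)]

  fm <- extract_raw_features(cohort$sessions, schema,
    child_ids = children$child_id
  )
  fm <- derive_features(fm, schema)
  fm <- impute_missing(fm, schema)
  n_full <- nrow(fm$meta)
  sk <- skew_transform(fm, threshold = config$skew_threshold,
    fit_ids = train_ids
  )
  fm <- sk$features
  fm <- prune_correlated(fm, r_max = config$r_max, fit_ids = train_ids)
  n_pruned <- nrow(fm$meta)
  # outcome must align with the fit rows in child order
  idx <- fit_row_idx(fm, train_ids)
  y <- children$bsid_cognitive_raw[match(fm$data$child_id[idx], children$child_id)]
  subset <- config$interaction_subset
  if (is.null(subset)) {
    subset <- choose_interaction_subset(
      fm, y, n = config$interaction_subset_size, fit_ids = train_ids
    )
  }
  fm <- build_interactions(fm, subset,
    r_max = config$r_max, null_max = config$null_max, fit_ids = train_ids
  )
  n_inter <- nrow(fm$meta) - n_pruned
  fm <- mas_o_menos(fm, y, fit_ids = train_ids)
  fm <- pca_features(fm, var_target = config$pca_var_target,
    fit_ids = train_ids
  )
  n_pca <- sum(fm$meta$stage == "pca")
  fm <- scale_features(fm, fit_ids = train_ids)
  attr(fm, "composition") <- tibble::tibble(
    stage = c("extracted+derived", "pruned", "interaction", "mom", "pca",
              "total"),
    n_features = c(n_full, n_pruned, n_inter, 1L, n_pca,
                   n_pruned + n_inter + 1L + n_pca)
  )
  attr(fm, "interaction_subset") <- subset
  attr(fm, "skew_log") <- sk$log
  fm
}

#' Per-stage composition of an assembled feature set
#'
#' @param fm Output of [assemble_feature_set()].
#' @return The composition tibble (stage, n_features).
#' @export
feature_report <- function(fm) attr(fm, "composition")
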