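#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the base models of a fitted ensemble
#'
#' @param x A `deep_ensemble`.
#' @param ... Unused.
#' @return Tibble with one row per base model: selector, learner, number
#'   of selected features, and out-of-fold holdout correlation.
#' @export
tidy.deep_ensemble <- function(x, ...) {
  purrr::list_rbind(purrr::map(x$base_models, function(b) {
    tibble::tibble(
      selector = b$selector, learner = b$learner, model = b$model,
      n_features = length(b$features), holdout_r = b$holdout_r,
      features = list(b$features)
    )
  }))
}

#' @rdname tidy.deep_ensemble
#' @export
glance.deep_ensemble <- function(x, ...) {
  tibble::tibble(
    n_base_models = length(x$base_models),
    n_stackers = length(x$stackers),
    weight_linear = unname(x$weights[1]),
    weight_rf = unname(x$weights[2]),
    weight_xgb = unname(x$weights[3]),
    n_train = length(x$train_ids),
    support_min = min(x$support),
    support_max = max(x$support)
  )
}

#' Tidy an evaluation into one row per split and metric
#'
#' @param x A `deep_evaluation`.
#' @param ... Unused.
#' @return A long tibble: `split`, `metric`, `estimate`, `conf_low`,
#'   `conf_high` where available.
#' @export
tidy.deep_evaluation <- function(x, ...) {
  ag <- x$agreement
  rc <- x$roc
  rows <- purrr::map(seq_len(nrow(ag)), function(i) {
    tibble::tibble(
      split = ag$split[i],
      metric = c("pearson_r", "icc_2_1", "mae", "rmse", "bias",
                 "auc", "sensitivity", "specificity", "accuracy"),
      estimate = c(
        ag$pearson_r[i], ag$icc[i], ag$mae[i], ag$rmse[i], ag$bias[i],
        rc$auc[i], rc$sensitivity[i], rc$specificity[i], rc$accuracy[i]
      ),
      conf_low = c(ag$pearson_low[i], ag$icc_low[i], rep(NA_real_, 7)),
      conf_high = c(ag$pearson_high[i], ag$icc_high[i], rep(NA_real_, 7))
    )
  })
  purrr::list_rbind(rows)
}

#' @rdname tidy.deep_evaluation
#' @export
glance.deep_evaluation <- function(x, ...) {
  ag <- x$agreement
  rc <- x$roc
  tr <- which(ag$split == "train")
  te <- which(ag$split == "test")
  tibble::tibble(
    r_train = ag$pearson_r[tr], r_test = ag$pearson_r[te],
    icc_train = ag$icc[tr], icc_test = ag$icc[te],
    mae_train = ag$mae[tr], mae_test = ag$mae[te],
    auc_train = rc$auc[rc$split == "train"],
    auc_test = rc$auc[rc$split == "test"],
    cutoff = x$cutoff, bsid_threshold = x$bsid_threshold,
    n_excluded = length(x$excluded)
  )
}
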