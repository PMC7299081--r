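# Feature-selection registry. Every selector maps (x, y, cap) -> at most
# `cap` column names of x; all are deterministic given the RNG state, and
# stochastic ones (forests, boosting) reseed from their `seed` argument.

top_by <- function(score, x, cap) {
  score[is.na(score)] <- -Inf
  ord <- order(-score, colnames(x))
  colnames(x)[ord][seq_len(min(cap, sum(is.finite(score) & score > -Inf)))]
}

select_correlation <- function(x, y, cap, seed = 0) {
  r <- suppressWarnings(abs(as.vector(stats::cor(x, y))))
  top_by(r, x, cap)
}

glmnet_path_select <- function(x, y, cap, alpha) {
  fit <- glmnet::glmnet(x, y, alpha = alpha, nlambda = 60)
  nz <- fit$df
  # densest model along the path still within the cap
  ok <- which(nz <= cap & nz > 0)
  if (length(ok) == 0) return(select_correlation(x, y, cap))
  lam <- ok[which.max(nz[ok])]
  beta <- fit$beta[, lam]
  names(beta)[beta != 0]
}

select_lasso <- function(x, y, cap, seed = 0) glmnet_path_select(x, y, cap, 1)

select_elastic_net <- function(x, y, cap, seed = 0) glmnet_path_select(x, y, cap, 0.5)

select_rf_importance <- function(x, y, cap, seed = 0) {
  fit <- ranger::ranger(
    x = x, y = y, num.trees = 150, importance = "impurity",
    seed = seed, num.threads = 1, respect.unordered.factors = FALSE
  )
  top_by(fit$variable.importance, x, cap)
}

select_gb_importance <- function(x, y, cap, seed = 0) {
  fit <- xgboost::xgb.train(
    params = list(
      eta = 0.3, max_depth = 3, nthread = 1, seed = seed,
      objective = "reg:squarederror"
    ),
    data = xgboost::xgb.DMatrix(x, label = y), nrounds = 40, verbose = 0
  )
  imp <- xgboost::xgb.importance(model = fit)
  if (nrow(imp) == 0) return(select_correlation(x, y, cap))
  utils::head(imp$Feature, cap)
}

# backward elimination on a linear model, after a correlation screen that
# keeps the fit overdetermined
select_rfe_linear <- function(x, y, cap, seed = 0) {
  screen <- select_correlation(x, y, min(40, nrow(x) - 10))
  feats <- screen
  while (length(feats) > cap) {
    fit <- stats::lm.fit(cbind(1, x[, feats, drop = FALSE]), y)
    coefs <- fit$coefficients[-1]
    se_proxy <- abs(coefs) * apply(x[, feats, drop = FALSE], 2, stats::sd)
    drop_n <- max(1, floor(length(feats) * 0.2))
    drop_n <- min(drop_n, length(feats) - cap)
    worst <- order(se_proxy, decreasing = FALSE)[seq_len(drop_n)]
    feats <- feats[-worst]
  }
  feats
}

# greedy minimum-redundancy-maximum-relevance on absolute correlations
select_mrmr <- function(x, y, cap, seed = 0) {
  pool <- select_correlation(x, y, min(120, ncol(x)))
  xs <- x[, pool, drop = FALSE]
  rel <- suppressWarnings(abs(as.vector(stats::cor(xs, y))))
  rel[is.na(rel)] <- 0
  cm <- suppressWarnings(abs(stats::cor(xs)))
  cm[is.na(cm)] <- 0
  chosen <- integer(0)
  for (step in seq_len(min(cap, ncol(xs)))) {
    if (length(chosen) == 0) {
      score <- rel
    } else {
      red <- rowMeans(cm[, chosen, drop = FALSE])
      score <- rel - red
    }
    score[chosen] <- -Inf
    chosen <- c(chosen, which.max(score))
  }
  pool[chosen]
}

#' The registered feature selectors
#'
#' Seven selection procedures, each returning at most `cap` feature names:
#' univariate-correlation top-k, LASSO path, elastic-net path (alpha 0.5),
#' random-forest impurity importance, gradient-boosting gain importance,
#' recursive feature elimination on a linear fit, and greedy
#' minimum-redundancy-maximum-relevance.
#'
#' @param which Optional character subset of selector names.
#' @return Named list of functions `(x, y, cap, seed)`.
#' @export
deep_selectors <- function(which = NULL) {
  all <- list(
    correlation = select_correlation,
    lasso = select_lasso,
    elastic_net = select_elastic_net,
    rf_importance = select_rf_importance,
    gb_importance = select_gb_importance,
    rfe_linear = select_rfe_linear,
    mrmr = select_mrmr
  )
  if (is.null(which)) all else all[which]
}
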