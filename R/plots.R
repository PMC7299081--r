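#' Bland-Altman agreement plot
#'
#' @param evaluation A `deep_evaluation`.
#' @return A ggplot: per-child difference against mean, with the bias line
#'   and the 1.96-SD limits of agreement.
#' @export
plot_bland_altman <- function(evaluation) {
  s <- evaluation$scores
  ba <- bland_altman_points(s$deep_score, s$bsid_cognitive_raw)
  df <- ba$points
  df$split <- s$split
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean, y = .data$diff,
                                   colour = .data$split)) +
    ggplot2::geom_hline(yintercept = ba$bias, linetype = "solid") +
    ggplot2::geom_hline(yintercept = ba$limits, linetype = "dashed") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(
      x = "Mean of predicted and benchmark score",
      y = "Predicted - benchmark",
      title = "Bland-Altman agreement",
      colour = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Empirical ROC curves for train and test children
#'
#' @param evaluation A `deep_evaluation`.
#' @return A ggplot of the empirical ROC curve per split, with the chosen
#'   cutoff marked.
#' @export
plot_roc <- function(evaluation) {
  s <- evaluation$scores
  curves <- purrr::map(c(train = "train", test = "test"), function(sp) {
    d <- s[s$split == sp, ]
    thr <- c(-Inf, sort(unique(d$deep_score)), Inf)
    pts <- purrr::map(thr, function(cc) {
      tibble::tibble(
        split = sp,
        fpr = mean(d$deep_score[!d$positive] < cc),
        tpr = mean(d$deep_score[d$positive] < cc),
        at_cutoff = FALSE
      )
    })
    purrr::list_rbind(pts)
  })
  df <- purrr::list_rbind(curves)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fpr, y = .data$tpr,
                                   colour = .data$split)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::geom_step() +
    ggplot2::labs(
      x = "False positive rate", y = "True positive rate",
      title = "Identifying low benchmark scorers", colour = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Distributions of predicted and benchmark scores
#'
#' @param evaluation A `deep_evaluation`.
#' @return A ggplot of overlaid histograms per split.
#' @export
plot_score_distributions <- function(evaluation) {
  s <- evaluation$scores
  df <- tidyr::pivot_longer(
    s[, c("split", "deep_score", "bsid_cognitive_raw")],
    cols = c("deep_score", "bsid_cognitive_raw"),
    names_to = "score", values_to = "value"
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$value, fill = .data$score)) +
    ggplot2::geom_histogram(position = "identity", alpha = 0.5,
                            binwidth = 1) +
    ggplot2::facet_wrap(~split) +
    ggplot2::labs(x = "Score", y = "Children", fill = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname plot_bland_altman
#' @param object A `deep_evaluation`.
#' @param type One of `"bland_altman"`, `"roc"`, `"distribution"`.
#' @param ... Unused.
#' @export
autoplot.deep_evaluation <- function(object,
                                     type = c("bland_altman", "roc",
                                              "distribution"),
                                     ...) {
  switch(match.arg(type),
    bland_altman = plot_bland_altman(object),
    roc = plot_roc(object),
    distribution = plot_score_distributions(object)
  )
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
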