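#' Plot an ROC curve
#'
#' @param object A `roc_result`.
#' @param ... Unused.
#' @return A ggplot object (1 - specificity vs sensitivity, with the chance
#'   diagonal).
#' @export
autoplot.roc_result <- function(object, ...) {
  tr <- object$trace
  ggplot2::ggplot(tr, ggplot2::aes(x = 1 - .data$spec, y = .data$sens)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "1 - specificity", y = "Sensitivity",
      title = sprintf("AUC = %.3f (%d+/%d-)", object$auc, object$n_pos,
                      object$n_neg)
    ) +
    ggplot2::theme_minimal()
}

#' Plot plasma pTau217 by stage
#'
#' Boxplots of pTau217 concentration across Braak or biological stages of a
#' staged cohort, on a log scale.
#'
#' @param staged A staged cohort from [stage_cohort()].
#' @param by Staging column (default `"biological_stage"`).
#' @return A ggplot object.
#' @export
plot_stage_distribution <- function(staged, by = "biological_stage") {
  stopifnot(by %in% names(staged))
  ggplot2::ggplot(staged,
                  ggplot2::aes(x = .data[[by]], y = .data$ptau217)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = "Plasma pTau217 (pg/ml)") +
    ggplot2::theme_minimal()
}

#' Plot the two-threshold triage zones
#'
#' @param object A `zone_classification`.
#' @param scores,labels The scores and truth labels that were classified.
#' @param ... Unused.
#' @return A ggplot object: scores by truth status, coloured by zone, with
#'   the two cutoffs drawn.
#' @export
autoplot.zone_classification <- function(object, scores, labels, ...) {
  df <- tibble::tibble(
    score = scores,
    status = factor(ifelse(as.logical(labels), "positive", "negative")),
    zone = object$zone
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$status, y = .data$score,
                                   colour = .data$zone)) +
    ggplot2::geom_jitter(width = 0.15, height = 0, size = 0.8) +
    ggplot2::geom_hline(yintercept = c(object$lower, object$upper),
                        linetype = "dotted") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = "Score", colour = "Zone") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
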