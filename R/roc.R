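#' Area under the ROC curve by the rank (Mann-Whitney) statistic
#'
#' AUC with the "higher score implies positive" orientation, computed as the
#' normalized Mann-Whitney U with tied pairs counted 1/2; this equals the
#' trapezoidal area under the empirical ROC curve exactly.
#'
#' @param scores Numeric scores.
#' @param labels Binary labels (logical, or 0/1).
#' @return AUC in `[0, 1]`.
#' @export
auc_rank <- function(scores, labels) {
  labels <- as.logical(labels)
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L) {
    stop("AUC requires at least one positive and one negative label",
         call. = FALSE)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Empirical ROC curve
#'
#' Candidate thresholds are the unique observed scores plus a sentinel above
#' the maximum (the "call nothing positive" operating point); the
#' classification rule is score >= threshold => predicted positive, so
#' chosen thresholds always fall on observed concentrations.
#'
#' @param scores Numeric finite scores.
#' @param labels Binary truth labels; both classes must be present.
#' @return A `roc_result`: list with `trace` (tibble of `threshold`, `sens`,
#'   `spec`), `auc`, `n_pos`, `n_neg` and the orientation note. `auc_ci` is
#'   filled by [roc_with_ci()].
#' @examples
#' roc <- roc_curve(c(0.1, 0.2, 0.3, 0.4), c(FALSE, FALSE, TRUE, TRUE))
#' roc$auc
#' @export
roc_curve <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels))
  if (any(!is.finite(scores))) stop("scores must be finite", call. = FALSE)
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L) {
    stop("ROC requires at least one positive and one negative label",
         call. = FALSE)
  }
  thr <- sort(unique(scores))
  thr <- c(thr, max(thr) + 1)  # sentinel: nothing predicted positive
  # counts of scores >= t for positives/negatives, via cumulative sums
  # over the sorted unique scores
  pos_counts <- rev(cumsum(rev(tabulate(match(scores[labels], thr),
                                        nbins = length(thr)))))
  neg_counts <- rev(cumsum(rev(tabulate(match(scores[!labels], thr),
                                        nbins = length(thr)))))
  sens <- pos_counts / n_pos
  spec <- 1 - neg_counts / n_neg
  structure(
    list(
      trace = tibble::tibble(threshold = thr, sens = sens, spec = spec),
      auc = auc_rank(scores, labels),
      auc_ci = NULL,
      n_pos = n_pos,
      n_neg = n_neg,
      orientation = "higher score => positive",
      scores = scores,
      labels = labels
    ),
    class = "roc_result"
  )
}

#' ROC curve with a bootstrap CI on the AUC
#'
#' @inheritParams roc_curve
#' @inheritParams bootstrap_ci
#' @return A `roc_result` with `auc_ci` set to the percentile bootstrap
#'   interval.
#' @export
roc_with_ci <- function(scores, labels, B = 1000, level = 0.95,
                        seed = NULL, method = c("bootstrap", "subsample")) {
  roc <- roc_curve(scores, labels)
  dat <- data.frame(scores = scores, labels = as.logical(labels))
  roc$auc_ci <- bootstrap_ci(
    function(d) auc_rank(d$scores, d$labels), dat,
    B = B, level = level, seed = seed, method = match.arg(method)
  )
  roc
}

op_point <- function(roc, i) {
  sens <- roc$trace$sens[i]
  spec <- roc$trace$spec[i]
  thr <- roc$trace$threshold[i]
  pred <- roc$scores >= thr
  m <- operating_metrics(pred, roc$labels)
  structure(
    list(
      threshold = thr, sens = sens, spec = spec,
      ppv = m$ppv, npv = m$npv, accuracy = m$accuracy,
      youden_j = sens + spec - 1
    ),
    class = "operating_point"
  )
}

#' Youden-optimal operating point
#'
#' Scans every candidate threshold of the ROC curve and returns the one
#' maximizing Youden's J = sens + spec - 1; ties are broken toward the
#' lowest threshold, i.e. toward higher sensitivity, the natural choice for
#' a screening assay.
#'
#' @param roc A `roc_result`.
#' @return An `operating_point`: `threshold`, `sens`, `spec`, `ppv`, `npv`,
#'   `accuracy`, `youden_j`. Predictive values are raw, never
#'   prevalence-adjusted.
#' @export
youden_point <- function(roc) {
  # integer-scaled J = TP*n_neg - FP*n_pos keeps ties exact, so the
  # lowest-threshold tie-break is not at the mercy of float rounding
  tp <- round(roc$trace$sens * roc$n_pos)
  fp <- round((1 - roc$trace$spec) * roc$n_neg)
  j_scaled <- tp * roc$n_neg - fp * roc$n_pos
  op_point(roc, which.max(j_scaled))  # first maximum = lowest threshold
}

#' Operating point at a fixed sensitivity or specificity
#'
#' `threshold_at_sensitivity()` returns the largest threshold whose
#' sensitivity still meets the target (maximizing specificity subject to the
#' constraint); `threshold_at_specificity()` returns the smallest threshold
#' whose specificity meets the target (maximizing sensitivity subject to the
#' constraint).
#'
#' @param roc A `roc_result`.
#' @param target Required sensitivity or specificity in `(0, 1]`.
#' @return An `operating_point`.
#' @export
threshold_at_sensitivity <- function(roc, target) {
  stopifnot(target > 0, target <= 1)
  ok <- which(roc$trace$sens >= target - 1e-12)
  if (length(ok) == 0L) {
    stop("sensitivity target ", target, " unattainable; maximum is ",
         max(roc$trace$sens), call. = FALSE)
  }
  op_point(roc, max(ok))
}

#' @rdname threshold_at_sensitivity
#' @export
threshold_at_specificity <- function(roc, target) {
  stopifnot(target > 0, target <= 1)
  ok <- which(roc$trace$spec >= target - 1e-12)
  if (length(ok) == 0L) {
    stop("specificity target ", target, " unattainable; maximum is ",
         max(roc$trace$spec), call. = FALSE)
  }
  op_point(roc, min(ok))
}

#' Confusion-matrix metrics for a binary prediction
#'
#' @param predicted Logical (or 0/1) predicted-positive indicator.
#' @param truth Logical truth labels; both classes must be present.
#' @return A tibble with `sens`, `spec`, `ppv`, `npv`, `accuracy`; ratios
#'   with a zero denominator are reported as `NA`, never as 0.
#' @export
operating_metrics <- function(predicted, truth) {
  predicted <- as.logical(predicted)
  truth <- as.logical(truth)
  if (length(predicted) != length(truth)) {
    stop("predicted and truth must have equal length", call. = FALSE)
  }
  if (!any(truth) || all(truth)) {
    stop("truth must contain both classes", call. = FALSE)
  }
  tp <- sum(predicted & truth)
  fp <- sum(predicted & !truth)
  tn <- sum(!predicted & !truth)
  fn <- sum(!predicted & truth)
  safe <- function(num, den) if (den == 0) NA_real_ else num / den
  tibble::tibble(
    sens = safe(tp, tp + fn),
    spec = safe(tn, tn + fp),
    ppv = safe(tp, tp + fp),
    npv = safe(tn, tn + fn),
    accuracy = (tp + tn) / length(truth)
  )
}

#' @export
print.roc_result <- function(x, ...) {
  cat("ROC:", x$n_pos, "positives /", x$n_neg, "negatives; AUC =",
      round(x$auc, 4))
  if (!is.null(x$auc_ci)) {
    cat(" [", round(x$auc_ci[1], 4), "-", round(x$auc_ci[2], 4), "]",
        sep = "")
  }
  cat("\n")
  invisible(x)
}

#' @export
print.operating_point <- function(x, ...) {
  cat(sprintf(
    "threshold %.4g: sens %.3f, spec %.3f, ppv %.3f, npv %.3f, acc %.3f (J = %.3f)\n",
    x$threshold, x$sens, x$spec, x$ppv, x$npv, x$accuracy, x$youden_j))
  invisible(x)
}
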