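#' Two-threshold triage into Low / Indeterminate / High zones
#'
#' Classifies each score against a lower (high-sensitivity) and an upper
#' (high-specificity) cutoff: score < lower is `Low`, score > upper is
#' `High`, and anything in between - including scores exactly on either
#' boundary - is `Indeterminate`. Agreement with the binary truth is
#' summarized only over the Low and High zones, excluding Indeterminate
#' cases: `pct_high_correct` is the fraction of High-zone records that are
#' truly positive, `pct_low_correct` the fraction of Low-zone records that
#' are truly negative, and `overall_correct` the pooled agreement over
#' Low and High.
#'
#' @param scores Numeric scores (e.g. plasma pTau217, pg/ml).
#' @param labels Binary truth labels (e.g. amyloid-PET positivity).
#' @param lower,upper Zone cutoffs with `lower <= upper`.
#' @return A `zone_classification` list: per-record `zone` factor, the
#'   cutoffs, `frac_low`/`frac_ind`/`frac_high` (summing to 1),
#'   `pct_high_correct`, `pct_low_correct`, `overall_correct`, and `n`.
#' @examples
#' z <- two_threshold_classify(c(0.10, 0.15, 0.20, 0.30),
#'                             c(FALSE, TRUE, FALSE, TRUE), 0.14, 0.23)
#' z$overall_correct
#' @export
two_threshold_classify <- function(scores, labels, lower, upper) {
  if (lower > upper) stop("lower cutoff exceeds upper cutoff", call. = FALSE)
  stopifnot(length(scores) == length(labels))
  labels <- as.logical(labels)
  zone <- factor(
    dplyr::case_when(
      scores < lower ~ "Low",
      scores > upper ~ "High",
      .default = "Indeterminate"
    ),
    levels = c("Low", "Indeterminate", "High")
  )
  n <- length(scores)
  n_low <- sum(zone == "Low")
  n_high <- sum(zone == "High")
  safe <- function(num, den) if (den == 0) NA_real_ else num / den
  structure(
    list(
      lower = lower, upper = upper, zone = zone, n = n,
      frac_low = n_low / n,
      frac_ind = sum(zone == "Indeterminate") / n,
      frac_high = n_high / n,
      pct_high_correct = safe(sum(zone == "High" & labels), n_high),
      pct_low_correct = safe(sum(zone == "Low" & !labels), n_low),
      overall_correct = safe(
        sum(zone == "High" & labels) + sum(zone == "Low" & !labels),
        n_low + n_high
      )
    ),
    class = "zone_classification"
  )
}

#' @export
print.zone_classification <- function(x, ...) {
  cat(sprintf(
    "zones [%.4g, %.4g]: low %.1f%%, indeterminate %.1f%%, high %.1f%%\n",
    x$lower, x$upper, 100 * x$frac_low, 100 * x$frac_ind, 100 * x$frac_high))
  cat(sprintf(
    "  correct: high %.1f%%, low %.1f%%, overall (excl. indeterminate) %.1f%%\n",
    100 * x$pct_high_correct, 100 * x$pct_low_correct,
    100 * x$overall_correct))
  invisible(x)
}
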