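#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy and glance methods
#'
#' Broom-style accessors: `tidy()` returns the per-threshold / per-term /
#' per-record detail of a fitted object as a tibble, `glance()` a one-row
#' summary.
#'
#' @param x A `roc_result`, `operating_point`, `zone_classification`,
#'   `logistic_fit` or `group_comparison` object.
#' @param ... Unused.
#' @return A tibble.
#' @name ptau217-tidiers
NULL

#' @rdname ptau217-tidiers
#' @export
tidy.roc_result <- function(x, ...) {
  x$trace
}

#' @rdname ptau217-tidiers
#' @export
glance.roc_result <- function(x, ...) {
  tibble::tibble(
    auc = x$auc,
    auc_lo = if (is.null(x$auc_ci)) NA_real_ else x$auc_ci[1],
    auc_hi = if (is.null(x$auc_ci)) NA_real_ else x$auc_ci[2],
    n_pos = x$n_pos, n_neg = x$n_neg
  )
}

#' @rdname ptau217-tidiers
#' @export
tidy.operating_point <- function(x, ...) {
  tibble::tibble(
    threshold = x$threshold, sens = x$sens, spec = x$spec, ppv = x$ppv,
    npv = x$npv, accuracy = x$accuracy, youden_j = x$youden_j
  )
}

#' @rdname ptau217-tidiers
#' @export
tidy.zone_classification <- function(x, ...) {
  tibble::tibble(zone = x$zone)
}

#' @rdname ptau217-tidiers
#' @export
glance.zone_classification <- function(x, ...) {
  tibble::tibble(
    lower = x$lower, upper = x$upper, n = x$n,
    frac_low = x$frac_low, frac_ind = x$frac_ind, frac_high = x$frac_high,
    pct_low_correct = x$pct_low_correct,
    pct_high_correct = x$pct_high_correct,
    overall_correct = x$overall_correct
  )
}

#' @rdname ptau217-tidiers
#' @export
tidy.logistic_fit <- function(x, ...) {
  tibble::tibble(term = names(x$coefficients),
                 estimate = unname(x$coefficients))
}

#' @rdname ptau217-tidiers
#' @export
glance.logistic_fit <- function(x, ...) {
  tibble::tibble(n = x$n, converged = x$converged,
                 separation_flag = x$separation_flag)
}

#' @rdname ptau217-tidiers
#' @export
tidy.group_comparison <- function(x, ...) {
  x$pairwise
}

#' @rdname ptau217-tidiers
#' @export
glance.group_comparison <- function(x, ...) {
  x$omnibus
}
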