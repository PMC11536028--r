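#' Tau positivity cutoff as mean + k SD of a reference sample
#'
#' The primary tau positivity rule: a composite SUVR is called positive when
#' it exceeds the mean plus `k` standard deviations (sample SD, n - 1
#' denominator) of the amyloid-negative cognitively unimpaired reference
#' stratum.
#'
#' @param values Numeric SUVR values from the reference stratum (>= 2).
#' @param k SD multiplier (default 2.5).
#' @return The cutoff `mean(values) + k * sd(values)`.
#' @export
tau_threshold_mean_sd <- function(values, k = 2.5) {
  values <- as.numeric(values)
  if (length(values) < 2L) {
    stop("mean + k*SD threshold needs at least 2 reference values",
         call. = FALSE)
  }
  mean(values) + k * sd(values)
}

#' Tau positivity cutoff as a percentile of a reference sample
#'
#' Alternative positivity rule: the `p`th percentile of the reference
#' stratum, using linear interpolation between order statistics (the
#' conventional "type 7" definition used by [stats::quantile()]).
#'
#' @param values Numeric SUVR values (>= 1).
#' @param p Percentile in `[0, 100]` (default 95).
#' @return The percentile cutoff.
#' @export
tau_threshold_percentile <- function(values, p = 95) {
  values <- as.numeric(values)
  if (length(values) < 1L) {
    stop("percentile threshold needs at least 1 reference value", call. = FALSE)
  }
  stopifnot(p >= 0, p <= 100)
  unname(quantile(values, probs = p / 100, type = 7, names = FALSE))
}

#' Derive the high-tau Te boundary from amyloid-positive impaired records
#'
#' High neocortical tau burden is defined as the upper quartile of the
#' temporoparietal (Te) composite SUVR among amyloid-positive participants
#' with MCI or dementia; this quartile is the boundary between moderate
#' (T_MOD) and high (T_HIGH) tau in biological staging. The published
#' boundary from the full reference imaging sample is 2.68 SUVR; pass
#' `te_high = "fixed"` to [build_thresholds()] to use it instead of
#' deriving one.
#'
#' @param cohort Cohort tibble; composites are added if absent.
#' @param cl_cutoff Centiloid cutoff defining amyloid positivity
#'   (`centiloid >= cl_cutoff`).
#' @return The 75th percentile (type 7) of qualifying Te SUVR values.
#' @export
derive_te_high <- function(cohort, cl_cutoff = 25) {
  if (!"Te" %in% names(cohort)) cohort <- add_composites(cohort)
  qual <- cohort$Te[cohort$centiloid >= cl_cutoff &
                      cohort$group %in% c("MCI", "dementia")]
  if (length(qual) < 4L) {
    stop("deriving the high-tau Te boundary needs at least 4 amyloid-positive ",
         "MCI/dementia records; found ", length(qual), call. = FALSE)
  }
  unname(quantile(qual, probs = 0.75, type = 7, names = FALSE))
}

#' Build the full threshold set for staging and evaluation
#'
#' Computes a tau positivity cutoff for every built-in composite ROI from the
#' amyloid-negative cognitively unimpaired (CU) reference stratum, by either
#' the mean + k SD rule (default, k = 2.5) or a percentile rule (default
#' 95th), records the Centiloid amyloid cutoff, and fixes or derives the
#' high-tau Te boundary.
#'
#' Optionally, records whose tau pattern suggests primary age-related
#' tauopathy (PART: amyloid-negative but mesial-temporal tau) can be removed
#' from the Braak-composite reference stratum: amyloid-negative records whose
#' Me composite exceeds a provisional Me cutoff are dropped and the Braak
#' cutoffs recomputed once. The published analysis excluded PART cases but
#' did not state its identification rule, so this stand-in rule is off by
#' default and clearly a choice of this package.
#'
#' Conventions: amyloid positivity is `centiloid >= cl_cutoff` (the stated
#' inequality); tau positivity is strictly greater than the cutoff.
#'
#' @param cohort Cohort tibble (composites added if absent).
#' @param cl_cutoff Centiloid cutoff (default 25; the published sensitivity
#'   analyses span 10-50).
#' @param tau_method `"mean_plus_k_sd"` or `"percentile"`.
#' @param k SD multiplier for the mean + k SD rule.
#' @param p Percentile for the percentile rule.
#' @param te_high `"fixed"` (use `te_high_value`) or `"derive"` (upper
#'   quartile via [derive_te_high()]).
#' @param te_high_value The fixed high-tau Te boundary (default 2.68 SUVR).
#' @param part_exclusion Apply the PART stand-in exclusion to the
#'   Braak-composite reference stratum.
#' @return A `threshold_set` list: `cl_cutoff`, `tau_cutoffs` (named numeric
#'   over composites), `te_high_cutoff`, `tau_method`, `k`/`p`, and
#'   `provenance` (reference stratum sizes).
#' @examples
#' cohort <- generate_cohort(cohort_config(seed = 1))
#' ths <- build_thresholds(cohort)
#' ths$tau_cutoffs[["MetaT"]]
#' @export
build_thresholds <- function(cohort, cl_cutoff = 25,
                             tau_method = c("mean_plus_k_sd", "percentile"),
                             k = 2.5, p = 95,
                             te_high = c("fixed", "derive"),
                             te_high_value = 2.68,
                             part_exclusion = FALSE) {
  tau_method <- match.arg(tau_method)
  te_high <- match.arg(te_high)
  if (!"Me" %in% names(cohort)) cohort <- add_composites(cohort)

  ref <- cohort[cohort$centiloid < cl_cutoff & cohort$group == "CU", ]
  if (nrow(ref) < 2L) {
    stop("reference stratum (amyloid-negative CU) has ", nrow(ref),
         " records; at least 2 are required", call. = FALSE)
  }
  comp_names <- names(composite_definitions())
  cut_one <- function(values) {
    if (tau_method == "mean_plus_k_sd") tau_threshold_mean_sd(values, k)
    else tau_threshold_percentile(values, p)
  }
  cutoffs <- vapply(comp_names, function(nm) cut_one(ref[[nm]]), numeric(1))

  braak_names <- grep("^Braak", comp_names, value = TRUE)
  n_part_excluded <- 0L
  if (part_exclusion) {
    part <- ref$Me > cutoffs[["Me"]]
    n_part_excluded <- sum(part)
    ref_braak <- ref[!part, ]
    if (nrow(ref_braak) >= 2L) {
      cutoffs[braak_names] <- vapply(
        braak_names, function(nm) cut_one(ref_braak[[nm]]), numeric(1)
      )
    }
  }

  te_high_cutoff <- if (te_high == "fixed") {
    te_high_value
  } else {
    derive_te_high(cohort, cl_cutoff)
  }
  te_high_cutoff <- max(te_high_cutoff, cutoffs[["Te"]])

  structure(
    list(
      cl_cutoff = cl_cutoff,
      tau_cutoffs = cutoffs,
      te_high_cutoff = te_high_cutoff,
      tau_method = tau_method,
      k = if (tau_method == "mean_plus_k_sd") k else NULL,
      p = if (tau_method == "percentile") p else NULL,
      provenance = list(
        n_reference = nrow(ref),
        n_part_excluded = n_part_excluded,
        te_high_mode = te_high
      )
    ),
    class = "threshold_set"
  )
}

#' Serialize a threshold set to and from JSON
#'
#' @param thresholds A `threshold_set` from [build_thresholds()].
#' @param path File path.
#' @return `read_thresholds_json()` returns a `threshold_set`;
#'   `write_thresholds_json()` returns `path` invisibly.
#' @export
write_thresholds_json <- function(thresholds, path) {
  x <- unclass(thresholds)
  x$tau_cutoffs <- as.list(x$tau_cutoffs)  # keep composite names in JSON
  jsonlite::write_json(x, path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_thresholds_json
#' @export
read_thresholds_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$tau_cutoffs <- unlist(raw$tau_cutoffs)
  structure(raw, class = "threshold_set")
}

#' @export
print.threshold_set <- function(x, ...) {
  cat("Threshold set\n")
  cat("  Amyloid positivity: Centiloid >=", x$cl_cutoff, "\n")
  cat("  Tau method:", x$tau_method,
      if (x$tau_method == "mean_plus_k_sd") paste0("(k = ", x$k, ")")
      else paste0("(p = ", x$p, ")"), "\n")
  cat("  Te high-tau boundary:", round(x$te_high_cutoff, 3), "SUVR\n")
  cat("  Tau cutoffs:\n")
  print(round(x$tau_cutoffs, 3))
  invisible(x)
}
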