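BRAAK_LEVELS <- c("0", "I", "II", "III", "IV", "V", "VI", "Atypical")
BRAAK_GROUPED <- c("0", "I-II", "III-IV", "V-VI", "Atypical")
BRAAK_DICHOTOMY <- c("low", "high", "Atypical")
BIO_LEVELS <- c(BIO_STAGES, "Atypical")

#' Compute per-record tau positivity profiles
#'
#' Evaluates every composite ROI against its cutoff (strictly greater than)
#' and returns the positivity bits the staging rules consume: six ordered
#' Braak-composite bits plus Me/Te/R bits and the Te SUVR itself.
#'
#' @param cohort Cohort tibble (composites added if absent).
#' @param thresholds A `threshold_set` from [build_thresholds()].
#' @return A tibble with `id`, `braak1_pos`..`braak6_pos`, `me_pos`,
#'   `te_pos`, `r_pos`, `te_suvr`.
#' @export
tau_profiles <- function(cohort, thresholds) {
  if (!"Me" %in% names(cohort)) cohort <- add_composites(cohort)
  cuts <- thresholds$tau_cutoffs
  braak <- paste0("Braak", c("I", "II", "III", "IV", "V", "VI"))
  miss <- setdiff(c(braak, "Me", "Te", "R"), names(cohort))
  if (length(miss)) {
    stop("cohort lacks composite column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  out <- tibble::tibble(id = cohort$id)
  for (j in seq_along(braak)) {
    out[[paste0("braak", j, "_pos")]] <- cohort[[braak[j]]] > cuts[[braak[j]]]
  }
  out$me_pos <- cohort$Me > cuts[["Me"]]
  out$te_pos <- cohort$Te > cuts[["Te"]]
  out$r_pos <- cohort$R > cuts[["R"]]
  out$te_suvr <- cohort$Te
  out
}

#' Assign PET-based Braak stages from positivity profiles
#'
#' A record's Braak stage is the "latest" positive Braak composite provided
#' all earlier composites are also positive: an all-negative profile is stage
#' 0, a positive prefix of length k is stage k (I-VI), and any profile with a
#' positive composite preceded by a negative one is `Atypical`. The grouped
#' (I-II / III-IV / V-VI) and dichotomized (low = 0-III, high = IV-VI)
#' summaries used for reporting and ROC analyses are pure functions of the
#' stage.
#'
#' @param profiles Tibble from [tau_profiles()] (or any table with
#'   `braak1_pos`..`braak6_pos` logical columns).
#' @return The input with `braak_stage`, `braak_grouped`, `braak_dichotomy`
#'   factor columns appended.
#' @examples
#' p <- tibble::tibble(braak1_pos = TRUE, braak2_pos = TRUE,
#'                     braak3_pos = TRUE, braak4_pos = FALSE,
#'                     braak5_pos = FALSE, braak6_pos = FALSE)
#' assign_braak(p)$braak_stage
#' @export
assign_braak <- function(profiles) {
  bits <- as.matrix(profiles[paste0("braak", 1:6, "_pos")])
  storage.mode(bits) <- "logical"
  stage <- apply(bits, 1L, function(b) {
    k <- sum(b)
    if (all(b[seq_len(k)])) BRAAK_LEVELS[k + 1L] else "Atypical"
  })
  profiles$braak_stage <- factor(stage, levels = BRAAK_LEVELS)
  profiles$braak_grouped <- braak_group(profiles$braak_stage)
  profiles$braak_dichotomy <- braak_dichotomize(profiles$braak_stage)
  profiles
}

#' @rdname assign_braak
#' @param stage A factor/character vector of Braak stages.
#' @export
braak_group <- function(stage) {
  map <- c("0" = "0", I = "I-II", II = "I-II", III = "III-IV", IV = "III-IV",
           V = "V-VI", VI = "V-VI", Atypical = "Atypical")
  factor(unname(map[as.character(stage)]), levels = BRAAK_GROUPED)
}

#' @rdname assign_braak
#' @export
braak_dichotomize <- function(stage) {
  map <- c("0" = "low", I = "low", II = "low", III = "low",
           IV = "high", V = "high", VI = "high", Atypical = "Atypical")
  factor(unname(map[as.character(stage)]), levels = BRAAK_DICHOTOMY)
}

#' Assign biological AD stages from amyloid status and tau profile
#'
#' Implements the revised biological staging by amyloid positivity and the
#' extent/magnitude of tau:
#' * `A-T-`: amyloid-negative, Me/Te/R all tau-negative;
#' * `Initial` (A+T-): amyloid-positive, all tau-negative;
#' * `Early` (A+T_MTL+): amyloid-positive, tau limited to the mesial
#'   temporal lobe (Me positive, Te and R negative);
#' * `Intermediate` (A+T_MOD+): amyloid-positive, Te positive with Te SUVR
#'   at or below the high-tau boundary (regardless of Me/R);
#' * `Advanced` (A+T_HIGH+): amyloid-positive, Te SUVR above the high-tau
#'   boundary;
#' * `Atypical`: everything else, including any amyloid-negative record with
#'   tau positivity and amyloid-positive records with R-positive but
#'   Te-negative tau.
#'
#' @param cohort Cohort tibble with `centiloid` (composites added if absent).
#' @param thresholds A `threshold_set`.
#' @param profiles Optional precomputed [tau_profiles()]; must come from the
#'   same threshold set.
#' @return The profiles tibble with `abeta_pos` and `biological_stage`
#'   appended.
#' @export
assign_biological <- function(cohort, thresholds, profiles = NULL) {
  if (is.null(profiles)) profiles <- tau_profiles(cohort, thresholds)
  stopifnot(nrow(profiles) == nrow(cohort))
  a <- cohort$centiloid >= thresholds$cl_cutoff
  t_neg <- !profiles$me_pos & !profiles$te_pos & !profiles$r_pos
  te_hi <- profiles$te_suvr > thresholds$te_high_cutoff

  stage <- dplyr::case_when(
    !a & t_neg ~ "A-T-",
    a & t_neg ~ "Initial",
    a & profiles$me_pos & !profiles$te_pos & !profiles$r_pos ~ "Early",
    a & profiles$te_pos & !te_hi ~ "Intermediate",
    a & profiles$te_pos & te_hi ~ "Advanced",
    .default = "Atypical"
  )
  profiles$abeta_pos <- a
  profiles$biological_stage <- factor(stage, levels = BIO_LEVELS)
  profiles
}

#' Stage a cohort end to end
#'
#' Convenience wrapper: adds composites, computes profiles, and appends Braak
#' and biological stage assignments to the cohort.
#'
#' @inheritParams assign_biological
#' @return The cohort tibble with composites, positivity bits, Braak stage
#'   columns, `abeta_pos` and `biological_stage`.
#' @export
stage_cohort <- function(cohort, thresholds) {
  cohort <- if ("Me" %in% names(cohort)) cohort else add_composites(cohort)
  prof <- assign_braak(tau_profiles(cohort, thresholds))
  prof <- assign_biological(cohort, thresholds, profiles = prof)
  dplyr::bind_cols(cohort, prof[setdiff(names(prof), "id")])
}

#' Per-stage counts and plasma pTau217 summaries
#'
#' Partitions the cohort into biological stages (or any staging column) and
#' summarizes plasma pTau217 as median and interquartile range per stage.
#' Counts always partition the cohort: every record lands in exactly one
#' category, including `Atypical`.
#'
#' @param staged A staged cohort from [stage_cohort()] (or a cohort plus a
#'   `by` column).
#' @param by Staging column to tabulate (default `"biological_stage"`).
#' @param group_braak_12 Merge Braak stages I and II into "I-II" for
#'   reporting (only meaningful with `by = "braak_stage"`).
#' @return A tibble with `stage`, `n`, `ptau_median`, `ptau_q1`, `ptau_q3`.
#' @export
stage_table <- function(staged, by = "biological_stage",
                        group_braak_12 = FALSE) {
  stopifnot(nrow(staged) > 0, by %in% names(staged))
  key <- staged[[by]]
  if (group_braak_12 && by == "braak_stage") {
    key <- as.character(key)
    key[key %in% c("I", "II")] <- "I-II"
    key <- factor(key, levels = c("0", "I-II", "III", "IV", "V", "VI",
                                  "Atypical"))
  }
  tibble::tibble(stage = key, ptau217 = staged$ptau217) |>
    dplyr::group_by(stage = .data$stage, .drop = FALSE) |>
    dplyr::summarise(
      n = dplyr::n(),
      ptau_median = if (dplyr::n() > 0) median(.data$ptau217) else NA_real_,
      ptau_q1 = if (dplyr::n() > 0) quantile(.data$ptau217, 0.25, names = FALSE)
                else NA_real_,
      ptau_q3 = if (dplyr::n() > 0) quantile(.data$ptau217, 0.75, names = FALSE)
                else NA_real_,
      .groups = "drop"
    )
}

#' Write the per-record staging table
#'
#' Writes `staging.csv`: id, Braak stage, grouped stage, dichotomy,
#' biological stage, plus the positivity bits.
#'
#' @param staged A staged cohort from [stage_cohort()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_staging_csv <- function(staged, path) {
  cols <- c("id", "braak_stage", "braak_grouped", "braak_dichotomy",
            "biological_stage", paste0("braak", 1:6, "_pos"),
            "me_pos", "te_pos", "r_pos")
  utils::write.csv(staged[cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
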