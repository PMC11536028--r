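#' Published summary numbers used as calibration anchors
#'
#' Returns the printed cohort summary statistics that the synthetic generator
#' is calibrated against and that the reporting helpers
#' ([prevalence_summary()], [fold_change_summary()]) can be checked against:
#' per-cell sample sizes and amyloid-PET positivity counts, plasma pTau217
#' medians by clinical group x amyloid status, by PET-based Braak stage, and
#' by biological stage.
#'
#' These are fixed published numbers, not quantities this package computes;
#' they function as inputs (targets for [calibration_report()], numerators
#' and denominators for arithmetic summaries), never as outputs.
#'
#' @return A named list of tibbles: `cells` (clinical group x amyloid status
#'   with `n` and pTau217 `ptau_median`), `braak_medians`, `stage_medians`
#'   (biological stages with published group sizes), and `thresholds`
#'   (Centiloid cutoff 25, Te high-tau boundary 2.68 SUVR, two-threshold
#'   triage cutoffs 0.14/0.23 pg/ml).
#' @export
reference_summaries <- function() {
  list(
    cells = tibble::tribble(
      ~group,     ~abeta, ~n,  ~ptau_median,
      "CU",       FALSE,  94L, 0.1,
      "CU",       TRUE,   62L, 0.2,
      "MCI",      FALSE,  31L, 0.1,
      "MCI",      TRUE,   69L, 0.4,
      "dementia", FALSE,  15L, 0.1,
      "dementia", TRUE,   117L, 0.6
    ),
    braak_medians = tibble::tribble(
      ~stratum,    ~target,
      "Braak0",    0.1,
      "BraakI-II", 0.2,
      "BraakIII",  0.3,
      "BraakIV",   0.4,
      "BraakV",    0.6,
      "BraakVI",   0.8
    ),
    stage_medians = tibble::tribble(
      ~stratum,       ~target, ~n,
      "A-T-",         0.1,     136L,
      "Initial",      0.2,     96L,
      "Early",        0.4,     15L,
      "Intermediate", 0.6,     79L,
      "Advanced",     0.9,     57L
    ),
    thresholds = tibble::tibble(
      centiloid_cutoff = 25,
      te_high_suvr = 2.68,
      triage_lower = 0.14,
      triage_upper = 0.23
    )
  )
}
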