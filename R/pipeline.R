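#' Configuration for the end-to-end analysis pipeline
#'
#' @param cl_cutoff Primary Centiloid cutoff for amyloid positivity
#'   (default 25).
#' @param cl_sweep Additional Centiloid cutoffs for the ROC sensitivity
#'   sweep; all must lie in `[10, 50]`.
#' @param tau_method,k,p Tau-threshold rule passed to [build_thresholds()].
#' @param te_high,te_high_value High-tau Te boundary mode (fixed 2.68 SUVR
#'   by default, or derived as the amyloid-positive MCI/dementia upper
#'   quartile).
#' @param B,level Bootstrap replicates and CI coverage.
#' @param seed Integer seed controlling every random draw in the run.
#' @param zone_sens Sensitivity targets for the lower triage threshold
#'   (both 0.90 and 0.95 are evaluated by default).
#' @param zone_spec Specificity target for the upper triage threshold.
#' @return An `analysis_config` list.
#' @export
analysis_config <- function(cl_cutoff = 25,
                            cl_sweep = c(10, 20, 25, 30, 40, 50),
                            tau_method = "mean_plus_k_sd", k = 2.5, p = 95,
                            te_high = "fixed", te_high_value = 2.68,
                            B = 1000, level = 0.95, seed = 1L,
                            zone_sens = c(0.90, 0.95), zone_spec = 0.90) {
  if (any(cl_sweep < 10 | cl_sweep > 50)) {
    stop("cl_sweep values must lie in [10, 50]", call. = FALSE)
  }
  stopifnot(all(zone_sens > 0 & zone_sens <= 1), zone_spec > 0, zone_spec <= 1)
  structure(
    list(cl_cutoff = cl_cutoff, cl_sweep = sort(unique(c(cl_sweep, cl_cutoff))),
         tau_method = tau_method, k = k, p = p,
         te_high = te_high, te_high_value = te_high_value,
         B = B, level = level, seed = as.integer(seed),
         zone_sens = zone_sens, zone_spec = zone_spec),
    class = "analysis_config"
  )
}

subgroup_filter <- function(cohort, subgroup) {
  switch(subgroup,
         all = cohort,
         CU = cohort[cohort$group == "CU", ],
         CI = cohort[cohort$group %in% c("MCI", "dementia"), ])
}

#' Run the full plasma pTau217 evaluation pipeline
#'
#' Orchestrates the analysis over a cohort: threshold derivation, Braak and
#' biological staging, Spearman correlations of pTau217 with Centiloid and
#' tau SUVR (whole cohort and CU/CI subgroups), ROC suites for amyloid
#' status across the Centiloid sweep and for tau status per ROI under both
#' threshold rules, two-threshold triage, and stage-discrimination logistic
#' models (pTau217-only vs age+sex+APOE base vs full) compared by DeLong
#' tests with Bonferroni adjustment. Youden thresholds are re-derived within
#' each subgroup. Reruns with the same cohort and seed produce identical
#' results.
#'
#' @param cohort A cohort tibble (e.g. from [generate_cohort()] or
#'   [read_cohort_csv()]).
#' @param config An [analysis_config()].
#' @param out_dir Optional directory; when given, the report bundle
#'   (`thresholds.json`, `staging.csv`, `correlations.csv`,
#'   `roc_summary.csv`, `zones.csv`, `stage_models.csv`, `metadata.json`)
#'   is written there.
#' @return An `analysis_report` list with elements `thresholds`, `staged`,
#'   `stage_table`, `braak_table`, `correlations`, `roc_summary`, `zones`,
#'   `stage_models`, `metadata`.
#' @export
run_analysis <- function(cohort, config = analysis_config(), out_dir = NULL) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)

  cohort <- add_composites(cohort)
  thresholds <- build_thresholds(
    cohort, cl_cutoff = config$cl_cutoff, tau_method = config$tau_method,
    k = config$k, p = config$p, te_high = config$te_high,
    te_high_value = config$te_high_value
  )
  staged <- stage_cohort(cohort, thresholds)
  stage_tbl <- stage_table(staged, "biological_stage")
  braak_tbl <- stage_table(staged, "braak_stage", group_braak_12 = TRUE)

  correlations <- pipeline_correlations(staged, config)
  roc_summary <- pipeline_roc_summary(staged, config)
  zones <- pipeline_zones(staged, config)
  stage_models <- pipeline_stage_models(staged, config)

  metadata <- list(
    seed = config$seed,
    cl_cutoff = config$cl_cutoff,
    bootstrap_B = config$B,
    config_hash = rlang::hash(config),
    n = nrow(cohort)
  )
  report <- structure(
    list(thresholds = thresholds, staged = staged, stage_table = stage_tbl,
         braak_table = braak_tbl, correlations = correlations,
         roc_summary = roc_summary, zones = zones,
         stage_models = stage_models, metadata = metadata),
    class = "analysis_report"
  )
  if (!is.null(out_dir)) write_report_bundle(report, out_dir)
  report
}

pipeline_correlations <- function(staged, config) {
  targets <- list(centiloid = "centiloid", Me = "Me", Te = "Te",
                  MetaT = "MetaT")
  rows <- list()
  for (sub in c("all", "CU", "CI")) {
    d <- subgroup_filter(staged, sub)
    if (nrow(d) < 3) next
    for (nm in names(targets)) {
      ct <- spearman_cor(d$ptau217, d[[targets[[nm]]]], B = config$B,
                         level = config$level)
      rows[[length(rows) + 1L]] <- dplyr::mutate(
        ct, subgroup = sub, against = nm, .before = 1
      )
    }
  }
  p_raw <- 2 * pnorm(-abs(vapply(rows, function(r) {
    # large-sample z for Spearman under independence
    r$r * sqrt(r$n - 1)
  }, numeric(1))))
  out <- dplyr::bind_rows(rows)
  out$p_adj <- bonferroni(p_raw)
  out
}

roc_row <- function(scores, labels, config, ...) {
  roc <- roc_curve(scores, labels)
  ci <- bootstrap_ci(
    function(d) auc_rank(d$s, d$l),
    data.frame(s = scores, l = as.logical(labels)),
    B = config$B, level = config$level
  )
  yp <- youden_point(roc)
  tibble::tibble(
    ...,
    n_pos = roc$n_pos, n_neg = roc$n_neg,
    auc = roc$auc, auc_lo = ci[1], auc_hi = ci[2],
    youden_threshold = yp$threshold, sens = yp$sens, spec = yp$spec,
    ppv = yp$ppv, npv = yp$npv, accuracy = yp$accuracy
  )
}

pipeline_roc_summary <- function(staged, config) {
  rows <- list()
  for (sub in c("all", "CU", "CI")) {
    d <- subgroup_filter(staged, sub)
    for (cl in config$cl_sweep) {
      lab <- d$centiloid >= cl
      if (sum(lab) == 0 || sum(!lab) == 0) next
      rows[[length(rows) + 1L]] <- roc_row(
        d$ptau217, lab, config,
        predictor = "ptau217", outcome = "abeta_pos", subgroup = sub,
        definition = paste0("CL>=", cl), method = "centiloid"
      )
    }
  }
  # tau status per ROI under both threshold rules (whole cohort)
  for (method in c("mean_plus_k_sd", "percentile")) {
    ths <- build_thresholds(staged, cl_cutoff = config$cl_cutoff,
                            tau_method = method, k = config$k, p = config$p,
                            te_high = config$te_high,
                            te_high_value = config$te_high_value)
    for (roi in c("Me", "Te", "MetaT")) {
      lab <- staged[[roi]] > ths$tau_cutoffs[[roi]]
      if (sum(lab) == 0 || sum(!lab) == 0) next
      rows[[length(rows) + 1L]] <- roc_row(
        staged$ptau217, lab, config,
        predictor = "ptau217", outcome = paste0("tau_pos_", roi),
        subgroup = "all", definition = paste0(roi, " ", method),
        method = method
      )
    }
  }
  # low (0-III) vs high (IV-VI) Braak tau, atypicals excluded
  d <- staged[staged$braak_dichotomy != "Atypical", ]
  lab <- d$braak_dichotomy == "high"
  if (sum(lab) > 0 && sum(!lab) > 0) {
    rows[[length(rows) + 1L]] <- roc_row(
      d$ptau217, lab, config,
      predictor = "ptau217", outcome = "braak_high", subgroup = "all",
      definition = "Braak IV-VI vs 0-III", method = config$tau_method
    )
  }
  dplyr::bind_rows(rows)
}

pipeline_zones <- function(staged, config) {
  lab <- staged$abeta_pos
  roc <- roc_curve(staged$ptau217, lab)
  rows <- list()
  for (sens_target in config$zone_sens) {
    lower <- threshold_at_sensitivity(roc, sens_target)$threshold
    upper <- threshold_at_specificity(roc, config$zone_spec)$threshold
    z <- two_threshold_classify(staged$ptau217, lab, min(lower, upper),
                                max(lower, upper))
    rows[[length(rows) + 1L]] <- tibble::tibble(
      sens_target = sens_target, spec_target = config$zone_spec,
      lower = z$lower, upper = z$upper,
      frac_low = z$frac_low, frac_ind = z$frac_ind, frac_high = z$frac_high,
      pct_low_correct = z$pct_low_correct,
      pct_high_correct = z$pct_high_correct,
      overall_correct = z$overall_correct
    )
  }
  dplyr::bind_rows(rows)
}

stage_model_outcomes <- function(staged) {
  s <- staged$biological_stage
  list(
    "A+ vs A-T-" = list(
      keep = s != "Atypical",
      positive = s %in% c("Initial", "Early", "Intermediate", "Advanced")
    ),
    "MOD/HIGH vs rest" = list(
      keep = s != "Atypical",
      positive = s %in% c("Intermediate", "Advanced")
    ),
    "HIGH vs rest" = list(
      keep = s != "Atypical",
      positive = s == "Advanced"
    )
  )
}

pipeline_stage_models <- function(staged, config) {
  models <- list(
    ptau = positive ~ ptau217,
    base = positive ~ age + sex + apoe4,
    full = positive ~ ptau217 + age + sex + apoe4
  )
  rows <- list()
  delong_ps <- numeric(0)
  for (sub in c("all", "CI")) {
    d0 <- subgroup_filter(staged, sub)
    for (oname in names(stage_model_outcomes(d0))) {
      oc <- stage_model_outcomes(d0)[[oname]]
      d <- d0[oc$keep, ]
      d$positive <- oc$positive[oc$keep]
      cc <- stats::complete.cases(d[, c("ptau217", "age", "sex", "apoe4")])
      d <- d[cc, ]
      if (sum(d$positive) < 2 || sum(!d$positive) < 2) next
      scores <- purrr::map(models, function(f) fit_logistic(d, f)$fitted)
      aucs <- purrr::map_dbl(scores, auc_rank, labels = d$positive)
      cis <- purrr::map(scores, function(s) {
        bootstrap_ci(function(dd) auc_rank(dd$s, dd$l),
                     data.frame(s = s, l = d$positive),
                     B = config$B, level = config$level)
      })
      dl_base <- delong_compare(scores$ptau, scores$base, d$positive)
      dl_full <- delong_compare(scores$ptau, scores$full, d$positive)
      delong_ps <- c(delong_ps, dl_base$p, dl_full$p)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        subgroup = sub, outcome = oname,
        model = names(models),
        auc = unname(aucs),
        auc_lo = purrr::map_dbl(cis, 1), auc_hi = purrr::map_dbl(cis, 2),
        n_pos = sum(d$positive), n_neg = sum(!d$positive),
        delong_p_vs_ptau = c(NA, dl_base$p, dl_full$p)
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  m <- length(delong_ps)
  out$delong_p_adj <- ifelse(is.na(out$delong_p_vs_ptau), NA,
                             bonferroni(out$delong_p_vs_ptau, m))
  out
}

#' Ratios of stage medians to a reference stratum
#'
#' Computes fold changes of the per-stage pTau217 medians relative to a
#' reference stratum (the first row by default), reported to one decimal.
#'
#' @param stage_tbl A tibble with `stage` and `ptau_median` columns (e.g.
#'   from [stage_table()]).
#' @param reference Name of the reference stage (default the first row).
#' @return The input with a `fold_change` column appended.
#' @export
fold_change_summary <- function(stage_tbl, reference = NULL) {
  stopifnot(all(c("stage", "ptau_median") %in% names(stage_tbl)))
  if (is.null(reference)) reference <- as.character(stage_tbl$stage[1])
  ref <- stage_tbl$ptau_median[as.character(stage_tbl$stage) == reference]
  if (length(ref) != 1L || !is.finite(ref) || ref <= 0) {
    stop("reference stratum '", reference,
         "' missing or has non-positive median", call. = FALSE)
  }
  dplyr::mutate(stage_tbl,
                fold_change = round(.data$ptau_median / ref, 1))
}

round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Amyloid-PET positivity prevalence per clinical group
#'
#' Percentages of amyloid-positive participants per group and overall,
#' rounded to integers (half away from zero).
#'
#' @param cohort Cohort tibble with `group` and `centiloid`.
#' @param cl_cutoff Centiloid cutoff (positivity is `>= cl_cutoff`).
#' @return Tibble with `group` (including `"overall"`), `n`, `n_pos`,
#'   `prevalence_pct`.
#' @export
prevalence_summary <- function(cohort, cl_cutoff = 25) {
  stopifnot(nrow(cohort) > 0)
  pos <- cohort$centiloid >= cl_cutoff
  per <- tibble::tibble(group = as.character(cohort$group), pos = pos) |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(n = dplyr::n(), n_pos = sum(.data$pos),
                     .groups = "drop")
  out <- dplyr::bind_rows(
    per,
    tibble::tibble(group = "overall", n = nrow(cohort), n_pos = sum(pos))
  )
  out$prevalence_pct <- round_half_away(100 * out$n_pos / out$n)
  out
}

write_report_bundle <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(x) file.path(out_dir, x)
  write_thresholds_json(report$thresholds, fp("thresholds.json"))
  write_staging_csv(report$staged, fp("staging.csv"))
  utils::write.csv(report$correlations, fp("correlations.csv"),
                   row.names = FALSE)
  utils::write.csv(report$roc_summary, fp("roc_summary.csv"),
                   row.names = FALSE)
  utils::write.csv(report$zones, fp("zones.csv"), row.names = FALSE)
  utils::write.csv(report$stage_models, fp("stage_models.csv"),
                   row.names = FALSE)
  jsonlite::write_json(report$metadata, fp("metadata.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("Plasma pTau217 analysis report (n =", x$metadata$n, ")\n")
  cat("  Biological stage table:\n")
  print(x$stage_table)
  cat("  ROC summary rows:", nrow(x$roc_summary), "\n")
  cat("  Triage:\n")
  print(x$zones)
  invisible(x)
}
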