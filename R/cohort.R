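#' @keywords internal
"_PACKAGE"

#' @importFrom rlang .data
#' @importFrom stats median quantile rnorm rbinom rlnorm runif qnorm pnorm sd
NULL

# Canonical biological-stage labels, ordered by disease severity.
BIO_STAGES <- c("A-T-", "Initial", "Early", "Intermediate", "Advanced")
GROUPS <- c("CU", "MCI", "dementia")

#' Default configuration for the synthetic cohort generator
#'
#' The defaults encode the study conditions the generator emulates: clinical
#' group sizes 156/100/132 (CU/MCI/dementia), amyloid-PET positivity
#' prevalence 0.40/0.69/0.89 per group, biological-stage mixtures per
#' amyloid-positive group chosen to reproduce the published stage counts,
#' stage-wise plasma pTau217 medians (0.1/0.2/0.4/0.6/0.9 pg/ml for
#' A-T-/Initial/Early/Intermediate/Advanced), a two-component Centiloid
#' mixture (near-zero normal for amyloid-negative, shifted log-normal for
#' amyloid-positive), and tau-PET SUVR profiles that follow Braak prefix
#' ordering except for a configurable atypical fraction.
#'
#' @param n_per_group Named integer vector of participants per clinical group
#'   (`CU`, `MCI`, `dementia`); all at least 1.
#' @param abeta_prevalence Named per-group probability of amyloid-PET
#'   positivity.
#' @param centiloid_params Tibble with one row per (group, abeta) cell:
#'   columns `group`, `abeta` (logical), `location`, `scale`. For
#'   amyloid-negative cells, `location`/`scale` are the mean/SD of a normal
#'   truncated below -10 Centiloid; for amyloid-positive cells the Centiloid
#'   is `25 + lognormal(log(location), scale)`.
#' @param stage_mix Matrix (groups x A+ stages `Initial`..`Advanced`) of
#'   stage probabilities for amyloid-positive participants; rows sum to 1.
#'   Amyloid-negative participants are always stage `A-T-`.
#' @param ptau_stage_medians Named vector of pTau217 medians (pg/ml) per
#'   biological stage, strictly increasing across ordered stages.
#' @param ptau_log_sd Log-scale SD of the log-normal pTau217 draw.
#' @param suvr_baseline Named vector `c(mean=, sd=)` for tau-negative regional
#'   SUVR.
#' @param suvr_increment Named vector of mean SUVR elevation added to
#'   tau-involved regions, per stage (`Early`, `Intermediate`, `Advanced`).
#' @param suvr_increment_log_sd Log-scale SD of the per-record multiplicative
#'   jitter applied to the elevation.
#' @param atypical_rate Probability that a record with tau spread beyond
#'   Braak I is rewritten to an out-of-order profile (one interior Braak
#'   composite reset to baseline while later composites stay elevated).
#' @param covariate_params Tibble with one row per (group, abeta) cell:
#'   columns `group`, `abeta`, `age_mean`, `age_sd`, `male_prop`,
#'   `apoe4_prop`.
#' @param seed Integer RNG seed stored in the config; [generate_cohort()]
#'   uses it for every draw.
#' @return A validated `cohort_config` list.
#' @examples
#' cfg <- cohort_config(seed = 1)
#' cfg$n_per_group
#' @export
cohort_config <- function(n_per_group = c(CU = 156, MCI = 100, dementia = 132),
                          abeta_prevalence = c(CU = 0.40, MCI = 0.69,
                                               dementia = 0.89),
                          centiloid_params = default_centiloid_params(),
                          stage_mix = default_stage_mix(),
                          ptau_stage_medians = c(
                            "A-T-" = 0.1, Initial = 0.2, Early = 0.4,
                            Intermediate = 0.6, Advanced = 0.9
                          ),
                          ptau_log_sd = 0.45,
                          suvr_baseline = c(mean = 1.0, sd = 0.06),
                          suvr_increment = c(Early = 0.9, Intermediate = 0.9,
                                             Advanced = 2.4),
                          suvr_increment_log_sd = 0.12,
                          atypical_rate = 0.08,
                          covariate_params = default_covariate_params(),
                          seed = 20240388L) {
  cfg <- structure(
    list(
      n_per_group = n_per_group,
      abeta_prevalence = abeta_prevalence,
      centiloid_params = tibble::as_tibble(centiloid_params),
      stage_mix = stage_mix,
      ptau_stage_medians = ptau_stage_medians,
      ptau_log_sd = ptau_log_sd,
      suvr_baseline = suvr_baseline,
      suvr_increment = suvr_increment,
      suvr_increment_log_sd = suvr_increment_log_sd,
      atypical_rate = atypical_rate,
      covariate_params = tibble::as_tibble(covariate_params),
      seed = as.integer(seed)
    ),
    class = "cohort_config"
  )
  validate_cohort_config(cfg)
  cfg
}

#' @rdname cohort_config
#' @export
default_centiloid_params <- function() {
  tibble::tribble(
    ~group,     ~abeta, ~location, ~scale,
    "CU",       FALSE,  -0.3,      6,
    "MCI",      FALSE,  -0.9,      6,
    "dementia", FALSE,   2.5,      6,
    "CU",       TRUE,   54,        0.7,
    "MCI",      TRUE,   88,        0.7,
    "dementia", TRUE,   88,        0.7
  )
}

#' @rdname cohort_config
#' @export
default_stage_mix <- function() {
  m <- rbind(
    CU       = c(Initial = 0.65, Early = 0.10, Intermediate = 0.20,
                 Advanced = 0.05),
    MCI      = c(Initial = 0.30, Early = 0.05, Intermediate = 0.45,
                 Advanced = 0.20),
    dementia = c(Initial = 0.15, Early = 0.05, Intermediate = 0.40,
                 Advanced = 0.40)
  )
  m
}

#' @rdname cohort_config
#' @export
default_covariate_params <- function() {
  tibble::tribble(
    ~group,     ~abeta, ~age_mean, ~age_sd, ~male_prop, ~apoe4_prop,
    "CU",       FALSE,  74.7,      4.7,     0.51,       0.24,
    "CU",       TRUE,   76.2,      6.6,     0.47,       0.56,
    "MCI",      FALSE,  69.6,      8.2,     0.48,       0.29,
    "MCI",      TRUE,   75.5,      6.9,     0.59,       0.72,
    "dementia", FALSE,  71.4,      6.6,     0.67,       0.13,
    "dementia", TRUE,   70.0,      7.9,     0.50,       0.74
  )
}

validate_cohort_config <- function(cfg) {
  fail <- function(field, msg) {
    stop("invalid cohort config: field '", field, "' ", msg, call. = FALSE)
  }
  if (!setequal(names(cfg$n_per_group), GROUPS)) {
    fail("n_per_group", "must be named CU/MCI/dementia")
  }
  if (any(cfg$n_per_group < 1)) fail("n_per_group", "entries must all be >= 1")
  pr <- cfg$abeta_prevalence
  if (!setequal(names(pr), GROUPS) || any(pr < 0) || any(pr > 1)) {
    fail("abeta_prevalence", "must be per-group probabilities in [0, 1]")
  }
  sm <- cfg$stage_mix
  if (!is.matrix(sm) || !setequal(rownames(sm), GROUPS) ||
      !setequal(colnames(sm), BIO_STAGES[-1])) {
    fail("stage_mix", "must be a groups x (Initial..Advanced) matrix")
  }
  if (any(sm < 0) || any(sm > 1)) fail("stage_mix", "entries must be in [0, 1]")
  if (any(abs(rowSums(sm) - 1) > 1e-9)) fail("stage_mix", "rows must sum to 1")
  med <- cfg$ptau_stage_medians
  if (!identical(names(med), BIO_STAGES)) {
    fail("ptau_stage_medians", "must be named by the five ordered stages")
  }
  if (any(med <= 0) || any(diff(med) <= 0)) {
    fail("ptau_stage_medians",
         "must be positive and strictly increasing across stages")
  }
  if (cfg$ptau_log_sd <= 0) fail("ptau_log_sd", "must be > 0")
  if (cfg$suvr_baseline[["mean"]] <= 0 || cfg$suvr_baseline[["sd"]] < 0) {
    fail("suvr_baseline", "must have positive mean and non-negative sd")
  }
  if (!setequal(names(cfg$suvr_increment),
                c("Early", "Intermediate", "Advanced")) ||
      any(cfg$suvr_increment <= 0)) {
    fail("suvr_increment", "must be positive, named Early/Intermediate/Advanced")
  }
  if (cfg$atypical_rate < 0 || cfg$atypical_rate > 1) {
    fail("atypical_rate", "must be a probability in [0, 1]")
  }
  cp <- cfg$covariate_params
  need <- c("group", "abeta", "age_mean", "age_sd", "male_prop", "apoe4_prop")
  if (!all(need %in% names(cp)) || nrow(cp) != 6L) {
    fail("covariate_params", "must have one row per (group, abeta) cell")
  }
  if (any(cp$male_prop < 0 | cp$male_prop > 1) ||
      any(cp$apoe4_prop < 0 | cp$apoe4_prop > 1)) {
    fail("covariate_params", "proportions must be in [0, 1]")
  }
  invisible(cfg)
}

# Braak extent (number of consecutively involved Braak composites) sampled
# for each true biological stage. Early tau stays mesial-temporal
# (Braak I-III); Intermediate reaches temporoparietal cortex (IV-V);
# Advanced involves late neocortex (V-VI) at high magnitude.
stage_extent_support <- list(
  "A-T-" = 0L, Initial = 0L, Early = 1:3, Intermediate = 4:5, Advanced = 5:6
)

#' Generate a synthetic cohort
#'
#' Draws a cohort hierarchically: clinical group, then amyloid status, then
#' biological stage, then (Centiloid, regional tau SUVR profile, plasma
#' pTau217, covariates). Truth labels (`truth_abeta`, `truth_stage`,
#' `truth_braak_extent`, `truth_atypical`) are carried so downstream staging
#' and discrimination can be validated against known ground truth. The same
#' config (including its seed) always yields a bit-identical cohort.
#'
#' @param config A [cohort_config()].
#' @return A tibble with one row per participant: `id`, `group`, `age`,
#'   `sex`, `apoe4`, `centiloid`, `ptau217`, one `suvr_<region>` column per
#'   atlas region required by the composite registry, and `truth_*` columns.
#' @examples
#' cohort <- generate_cohort(cohort_config(seed = 42))
#' dplyr::count(cohort, group, truth_abeta)
#' @export
generate_cohort <- function(config = cohort_config()) {
  validate_cohort_config(config)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)

  group <- factor(rep(GROUPS, times = config$n_per_group[GROUPS]),
                  levels = GROUPS)
  n <- length(group)
  abeta <- rbinom(n, 1L, config$abeta_prevalence[as.character(group)]) == 1L

  stage <- rep("A-T-", n)
  pos <- which(abeta)
  for (i in pos) {
    stage[i] <- sample(BIO_STAGES[-1], 1L,
                       prob = config$stage_mix[as.character(group[i]), ])
  }
  stage <- factor(stage, levels = BIO_STAGES)

  extent <- vapply(as.character(stage), function(s) {
    supp <- stage_extent_support[[s]]
    if (length(supp) == 1L) supp else sample(supp, 1L)
  }, integer(1))

  # Centiloid from the per-(group, abeta) mixture component.
  cl_key <- paste(group, abeta)
  cp <- config$centiloid_params
  cp_key <- paste(cp$group, cp$abeta)
  loc <- cp$location[match(cl_key, cp_key)]
  scl <- cp$scale[match(cl_key, cp_key)]
  centiloid <- numeric(n)
  neg <- !abeta
  if (any(neg)) {
    # normal truncated below -10 CL via inverse CDF
    lo <- pnorm(-10, loc[neg], scl[neg])
    centiloid[neg] <- qnorm(lo + runif(sum(neg)) * (1 - lo),
                            loc[neg], scl[neg])
  }
  if (any(abeta)) {
    centiloid[abeta] <- 25 + rlnorm(sum(abeta), log(loc[abeta]), scl[abeta])
  }

  # Regional tau SUVR: baseline noise everywhere, plus a stage-scaled
  # elevation on every region belonging to Braak composites 1..extent.
  regions <- required_regions()
  defs <- composite_definitions()
  braak_names <- paste0("Braak", c("I", "II", "III", "IV", "V", "VI"))
  braak_regions <- purrr::map(defs[braak_names], "regions")
  base <- config$suvr_baseline
  suvr <- matrix(rnorm(n * length(regions), base[["mean"]], base[["sd"]]),
                 nrow = n, dimnames = list(NULL, regions))
  suvr[suvr < 0.5] <- 0.5  # SUVR is a positive ratio; floor guards rare tails

  elev <- rep(0, n)
  has_inc <- as.character(stage) %in% names(config$suvr_increment)
  elev[has_inc] <- config$suvr_increment[as.character(stage[has_inc])] *
    exp(rnorm(sum(has_inc), 0, config$suvr_increment_log_sd))

  atypical <- rep(FALSE, n)
  eligible <- extent >= 2L
  atypical[eligible] <- runif(sum(eligible)) < config$atypical_rate
  dropped_braak <- rep(NA_integer_, n)
  dropped_braak[atypical] <- vapply(extent[atypical], function(k) {
    sample.int(k - 1L, 1L)
  }, integer(1))

  for (i in which(extent > 0L)) {
    keep <- setdiff(seq_len(extent[i]), dropped_braak[i])
    regs <- unique(unlist(braak_regions[keep]))
    suvr[i, regs] <- suvr[i, regs] + elev[i]
  }

  ptau <- unname(config$ptau_stage_medians[as.character(stage)]) *
    exp(rnorm(n, 0, config$ptau_log_sd))

  cvp <- config$covariate_params
  cv_key <- paste(cvp$group, cvp$abeta)
  ci <- match(cl_key, cv_key)
  age <- rnorm(n, cvp$age_mean[ci], cvp$age_sd[ci])
  sex <- factor(ifelse(runif(n) < cvp$male_prop[ci], "male", "female"),
                levels = c("male", "female"))
  apoe4 <- runif(n) < cvp$apoe4_prop[ci]

  out <- tibble::tibble(
    id = sprintf("S%04d", seq_len(n)),
    group = group,
    age = round(age, 1),
    sex = sex,
    apoe4 = apoe4,
    centiloid = centiloid,
    ptau217 = ptau
  )
  out <- dplyr::bind_cols(out, tibble::as_tibble(suvr, .name_repair = ~paste0("suvr_", .x)))
  out$truth_abeta <- abeta
  out$truth_stage <- stage
  out$truth_braak_extent <- as.integer(extent)
  out$truth_atypical <- atypical
  out
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Compare generated stratum medians against target values
#'
#' For each target stratum, computes the median of a cohort column (plasma
#' pTau217 by default) among records in that stratum and the relative
#' deviation from the target. Strata with fewer than 5 records (including
#' empty strata) are flagged rather than dropped.
#'
#' @param cohort A cohort tibble.
#' @param targets A data frame with columns `stratum` and `target` (the
#'   reference median for that stratum).
#' @param stratum_col Name of the cohort column holding the stratum labels
#'   (default `"truth_stage"`); an unknown column name is an error.
#' @param value_col Name of the value column summarized (default
#'   `"ptau217"`).
#' @return A tibble with one row per target stratum: `stratum`, `n`,
#'   `generated`, `target`, `deviation` = (generated - target) / target, and
#'   `flagged`.
#' @export
calibration_report <- function(cohort, targets, stratum_col = "truth_stage",
                               value_col = "ptau217") {
  stopifnot(nrow(cohort) > 0)
  if (!stratum_col %in% names(cohort)) {
    stop("unknown stratum key: cohort has no column '", stratum_col, "'",
         call. = FALSE)
  }
  targets <- tibble::as_tibble(targets)
  stopifnot(all(c("stratum", "target") %in% names(targets)))
  strata <- as.character(cohort[[stratum_col]])
  vals <- cohort[[value_col]]
  purrr::pmap_dfr(targets, function(stratum, target, ...) {
    sel <- vals[strata == as.character(stratum)]
    n <- length(sel)
    gen <- if (n > 0) median(sel) else NA_real_
    tibble::tibble(
      stratum = as.character(stratum),
      n = n,
      generated = gen,
      target = target,
      deviation = if (n > 0) (gen - target) / target else NA_real_,
      flagged = n < 5
    )
  })
}

#' Read and write cohort CSV files
#'
#' The cohort interchange format is a UTF-8 CSV with a header row and one row
#' per participant: columns `id,group,age,sex,apoe4,centiloid,ptau217`, one
#' `suvr_<region>` column per atlas region, and optional `truth_*` columns
#' (synthetic cohorts only). On read, records are validated: every region
#' required by the built-in composite registry must be present, SUVR and
#' pTau217 must be positive, and `group` must be CU/MCI/dementia.
#'
#' @param cohort A cohort tibble.
#' @param path File path.
#' @return `read_cohort_csv()` returns a validated cohort tibble;
#'   `write_cohort_csv()` returns `path` invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  df <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE,
                                          fileEncoding = "UTF-8"))
  problems <- character(0)
  need <- c("id", "group", "age", "sex", "apoe4", "centiloid", "ptau217")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    problems <- c(problems, paste("missing column(s):",
                                  paste(miss, collapse = ", ")))
  }
  suvr_cols <- grep("^suvr_", names(df), value = TRUE)
  have <- normalize_region(sub("^suvr_", "", suvr_cols))
  missr <- setdiff(required_regions(), have)
  if (length(missr)) {
    problems <- c(problems, paste("missing required region(s):",
                                  paste(missr, collapse = ", ")))
  }
  if ("group" %in% names(df) && !all(df$group %in% GROUPS)) {
    problems <- c(problems, "group values outside CU/MCI/dementia")
  }
  if ("ptau217" %in% names(df) && any(!is.finite(df$ptau217) | df$ptau217 <= 0)) {
    problems <- c(problems, "ptau217 must be positive")
  }
  if (length(suvr_cols) && any(!is.finite(as.matrix(df[suvr_cols])) |
                               as.matrix(df[suvr_cols]) <= 0)) {
    problems <- c(problems, "all SUVR values must be positive")
  }
  if (length(problems)) {
    stop("cohort CSV failed validation:\n  - ",
         paste(problems, collapse = "\n  - "), call. = FALSE)
  }
  df$group <- factor(df$group, levels = GROUPS)
  df$sex <- factor(df$sex, levels = c("male", "female"))
  df$apoe4 <- as.logical(df$apoe4)
  if ("truth_stage" %in% names(df)) {
    df$truth_stage <- factor(df$truth_stage, levels = BIO_STAGES)
  }
  if ("truth_abeta" %in% names(df)) df$truth_abeta <- as.logical(df$truth_abeta)
  if ("truth_atypical" %in% names(df)) {
    df$truth_atypical <- as.logical(df$truth_atypical)
  }
  df
}
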