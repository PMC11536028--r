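test_that("generation is deterministic: same config and seed, same cohort", {
  cfg <- small_config(seed = 101L)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)
  # byte-for-byte after serialization
  expect_identical(serialize(a, NULL), serialize(b, NULL))
  c2 <- generate_cohort(small_config(seed = 102L))
  expect_false(identical(a$ptau217, c2$ptau217))
})

test_that("cohort has the contracted shape and truth labels", {
  cfg <- small_config(seed = 5L)
  cohort <- generate_cohort(cfg)
  expect_equal(nrow(cohort), sum(cfg$n_per_group))
  expect_equal(as.vector(table(cohort$group)[c("CU", "MCI", "dementia")]),
               unname(cfg$n_per_group[c("CU", "MCI", "dementia")]))
  expect_true(all(c("truth_abeta", "truth_stage", "truth_atypical")
                  %in% names(cohort)))
  expect_true(all(cohort$ptau217 > 0))
  suvr <- as.matrix(cohort[grep("^suvr_", names(cohort))])
  expect_true(all(suvr > 0))
  expect_true(all(required_regions() %in%
                    sub("^suvr_", "", colnames(suvr))))
  # amyloid-positive truth implies Centiloid above the cutoff by construction
  expect_true(all(cohort$centiloid[cohort$truth_abeta] > 25))
})

test_that("invalid configs fail with the offending field named", {
  expect_error(cohort_config(n_per_group = c(CU = 0, MCI = 10, dementia = 10)),
               "n_per_group")
  expect_error(cohort_config(abeta_prevalence = c(CU = 1.2, MCI = 0.5,
                                                  dementia = 0.5)),
               "abeta_prevalence")
  bad_mix <- default_stage_mix()
  bad_mix[1, ] <- c(0.5, 0.5, 0.5, 0.5)
  expect_error(cohort_config(stage_mix = bad_mix), "stage_mix")
  expect_error(
    cohort_config(ptau_stage_medians = c("A-T-" = 0.1, Initial = 0.2,
                                         Early = 0.2, Intermediate = 0.6,
                                         Advanced = 0.9)),
    "ptau_stage_medians"
  )
  expect_error(cohort_config(atypical_rate = 1.5), "atypical_rate")
})

test_that("pooled amyloid prevalence reproduces the 64% design condition", {
  # default group sizes 156/100/132 and prevalences 0.40/0.69/0.89
  pos <- 0L
  tot <- 0L
  for (s in 1:10) {
    cohort <- generate_cohort(cohort_config(seed = 2000L + s))
    pos <- pos + sum(cohort$centiloid >= 25)
    tot <- tot + nrow(cohort)
  }
  expect_lt(abs(pos / tot - 0.64), 0.03)
})

test_that("amyloid-negative tau-negative records have pTau217 near 0.1 pg/ml", {
  cohort <- generate_cohort(cohort_config(seed = 31L))
  atn <- cohort$ptau217[cohort$truth_stage == "A-T-"]
  expect_gte(median(atn), 0.08)
  expect_lte(median(atn), 0.12)
})

test_that("atypical_rate = 0 yields only prefix-consistent tau profiles", {
  cfg <- small_config(seed = 77L, atypical_rate = 0)
  cohort <- generate_cohort(cfg)
  expect_false(any(cohort$truth_atypical))
  ths <- fixed_thresholds(cut = 1.3)
  prof <- assign_braak(tau_profiles(add_composites(cohort), ths))
  # at a comfortably separated cutoff, no generated profile is out of order
  expect_false(any(prof$braak_stage == "Atypical"))
  # and the assigned prefix length matches the generated extent
  k <- as.integer(prof$braak_stage) - 1L  # levels 0..VI are 1..7
  expect_equal(k, cohort$truth_braak_extent)
})

test_that("stage-wise pTau217 medians are non-decreasing across stages", {
  cfg <- cohort_config(
    n_per_group = c(CU = 300, MCI = 300, dementia = 300),
    seed = 41L
  )
  cohort <- generate_cohort(cfg)
  med <- tapply(cohort$ptau217, cohort$truth_stage, median)
  med <- med[c("A-T-", "Initial", "Early", "Intermediate", "Advanced")]
  expect_true(all(table(cohort$truth_stage) >= 50 |
                    names(table(cohort$truth_stage)) %in% c("Early")))
  expect_true(all(diff(med) >= 0))
})

test_that("empirical AUC converges to the closed-form log-normal value", {
  # two log-normal pTau strata with known parameters
  set.seed(9)
  n <- 5000
  sdlog <- 0.45
  neg <- 0.1 * exp(rnorm(n, 0, sdlog))
  pos <- 0.6 * exp(rnorm(n, 0, sdlog))
  emp <- auc_rank(c(neg, pos), rep(c(FALSE, TRUE), each = n))
  expect_lt(abs(emp - lognormal_auc(0.1, 0.6, sdlog)), 0.01)
})

test_that("calibration_report computes deviations and flags small strata", {
  cohort <- manual_cohort(10, ptau217 = 0.1)
  cohort$truth_stage <- factor(rep("A-T-", 10),
                               levels = c("A-T-", "Initial", "Early",
                                          "Intermediate", "Advanced"))
  targets <- tibble::tibble(stratum = c("A-T-", "Advanced"),
                            target = c(0.1, 0.9))
  rep <- calibration_report(cohort, targets)
  expect_equal(rep$deviation[rep$stratum == "A-T-"], 0)
  expect_false(rep$flagged[rep$stratum == "A-T-"])
  # empty stratum: flagged row, no crash
  adv <- rep[rep$stratum == "Advanced", ]
  expect_true(adv$flagged)
  expect_true(is.na(adv$generated))
  expect_equal(adv$n, 0L)
  # unknown stratum key errors
  expect_error(calibration_report(cohort, targets, stratum_col = "nope"),
               "unknown stratum key")
})

test_that("generated stage medians track the printed targets within 25%", {
  targets <- reference_summaries()$stage_medians[, c("stratum", "target")]
  devs <- purrr::map(1:3, function(s) {
    cohort <- generate_cohort(cohort_config(seed = 500L + s))
    rep <- calibration_report(cohort, targets)
    rep$deviation[!rep$flagged]
  })
  expect_true(all(abs(unlist(devs)) < 0.25))
})

test_that("cohort CSV round-trips and rejects invalid files", {
  cohort <- generate_cohort(small_config(seed = 3L))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort_csv(cohort, path)
  back <- read_cohort_csv(path)
  expect_equal(nrow(back), nrow(cohort))
  expect_equal(back$ptau217, cohort$ptau217, tolerance = 1e-12)
  expect_identical(as.character(back$truth_stage),
                   as.character(cohort$truth_stage))

  # drop a required region column -> itemized validation error
  df <- utils::read.csv(path)
  df$suvr_entorhinal <- NULL
  utils::write.csv(df, path, row.names = FALSE)
  expect_error(read_cohort_csv(path), "entorhinal")
})
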