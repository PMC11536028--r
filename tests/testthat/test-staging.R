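braak_bits <- function(...) {
  b <- c(...)
  tibble::tibble(braak1_pos = b[1], braak2_pos = b[2], braak3_pos = b[3],
                 braak4_pos = b[4], braak5_pos = b[5], braak6_pos = b[6])
}

test_that("tau profiles use strict inequality against cutoffs", {
  cohort <- add_composites(manual_cohort(2, baseline = 1.0))
  ths <- fixed_thresholds(cut = 1.5)
  prof <- tau_profiles(cohort, ths)
  expect_false(any(as.matrix(prof[paste0("braak", 1:6, "_pos")])))
  expect_false(any(prof$me_pos | prof$te_pos | prof$r_pos))

  # SUVR exactly at the cutoff is negative by convention
  at_cut <- set_composite_regions(manual_cohort(1), 1,
                                  names(composite_definitions()), 1.5)
  prof2 <- tau_profiles(add_composites(at_cut), ths)
  expect_false(any(prof2$me_pos | prof2$te_pos | prof2$r_pos))

  # an isolated Braak I elevation flips only the first bit
  one <- set_composite_regions(manual_cohort(1), 1, "BraakI", 1.6)
  prof3 <- tau_profiles(add_composites(one), fixed_thresholds(cut = 1.2))
  bits <- as.logical(prof3[paste0("braak", 1:6, "_pos")])
  expect_equal(bits, c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE))
})

test_that("Braak assignment matches the brute-force rule on all 64 vectors", {
  grid <- expand.grid(rep(list(c(FALSE, TRUE)), 6))
  stages <- character(64)
  for (i in 1:64) {
    bits <- as.logical(grid[i, ])
    got <- assign_braak(braak_bits(bits))
    stages[i] <- as.character(got$braak_stage)
    expect_identical(stages[i], braak_oracle(bits))
  }
  # exactly 7 non-Atypical outcomes: stage 0 plus the six prefixes
  expect_equal(sum(stages != "Atypical"), 7)
  expect_setequal(stages[stages != "Atypical"],
                  c("0", "I", "II", "III", "IV", "V", "VI"))
})

test_that("grouping and dichotomy are pure functions of the stage", {
  a <- assign_braak(braak_bits(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE))
  expect_equal(as.character(a$braak_stage), "0")
  expect_equal(as.character(a$braak_dichotomy), "low")

  b <- assign_braak(braak_bits(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(as.character(b$braak_stage), "III")
  expect_equal(as.character(b$braak_grouped), "III-IV")
  expect_equal(as.character(b$braak_dichotomy), "low")

  d <- assign_braak(braak_bits(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE))
  expect_equal(as.character(d$braak_dichotomy), "high")

  e <- assign_braak(braak_bits(TRUE, FALSE, FALSE, TRUE, FALSE, FALSE))
  expect_equal(as.character(e$braak_stage), "Atypical")
  expect_equal(as.character(e$braak_grouped), "Atypical")
})

test_that("biological staging implements the amyloid x tau criteria", {
  ths <- fixed_thresholds(cut = 1.5, te_high = 2.68)
  mk <- function(centiloid, me = 1.0, te = 1.0, r = 1.0) {
    cohort <- manual_cohort(1, centiloid = centiloid)
    cohort <- set_composite_regions(cohort, 1, "Me", me)
    cohort <- set_composite_regions(cohort, 1, "Te", te)
    cohort <- set_composite_regions(cohort, 1, "R", r)
    add_composites(cohort)
  }
  bio <- function(...) {
    as.character(assign_biological(mk(...), ths)$biological_stage)
  }
  expect_equal(bio(0), "A-T-")
  expect_equal(bio(80), "Initial")                    # A+, all tau negative
  expect_equal(bio(80, me = 2.0), "Early")            # tau limited to MTL
  expect_equal(bio(80, me = 2.0, te = 2.0), "Intermediate")
  expect_equal(bio(80, te = 3.0), "Advanced")         # Te above 2.68
  expect_equal(bio(-2, me = 2.0), "Atypical")         # A- with tau
  expect_equal(bio(80, r = 2.0), "Atypical")          # R+ but Te-
  # boundary: Te exactly at the high cutoff stays Intermediate
  expect_equal(bio(80, te = 2.68), "Intermediate")
})

test_that("increasing Te SUVR never moves a record to an earlier stage", {
  ths <- fixed_thresholds(cut = 1.5, te_high = 2.68)
  order_of <- c("A-T-" = 1, Initial = 2, Early = 3, Intermediate = 4,
                Advanced = 5)
  te_grid <- c(1.0, 1.6, 2.0, 2.68, 2.9, 4.0)
  for (cl in c(0, 80)) {
    for (me in c(1.0, 2.0)) {
      stages <- vapply(te_grid, function(te) {
        cohort <- manual_cohort(1, centiloid = cl)
        cohort <- set_composite_regions(cohort, 1, "Me", me)
        cohort <- set_composite_regions(cohort, 1, "Te", te)
        as.character(assign_biological(add_composites(cohort),
                                       ths)$biological_stage)
      }, character(1))
      ranks <- order_of[stages]
      ranks[is.na(ranks)] <- NA  # Atypical excluded from the ordering claim
      ok <- !is.na(ranks)
      expect_true(all(diff(ranks[ok]) >= 0))
    }
  }
})

test_that("staging partitions any cohort exactly once per scheme", {
  cohort <- generate_cohort(small_config(seed = 19L))
  ths <- build_thresholds(add_composites(cohort))
  staged <- stage_cohort(cohort, ths)
  expect_equal(nrow(staged), nrow(cohort))
  expect_false(any(is.na(staged$braak_stage)))
  expect_false(any(is.na(staged$biological_stage)))
  tbl <- stage_table(staged)
  expect_equal(sum(tbl$n), nrow(cohort))
  btbl <- stage_table(staged, "braak_stage", group_braak_12 = TRUE)
  expect_equal(sum(btbl$n), nrow(cohort))
  # Early implies Me+ and Te-/R-
  early <- staged[staged$biological_stage == "Early", ]
  if (nrow(early) > 0) {
    expect_true(all(early$me_pos & !early$te_pos & !early$r_pos))
  }
})

test_that("stage_table summarizes pTau217 with median and IQR", {
  cohort <- manual_cohort(8, ptau217 = 0.1, centiloid = 0)
  staged <- stage_cohort(cohort, fixed_thresholds(cut = 1.5))
  tbl <- stage_table(staged)
  row <- tbl[tbl$stage == "A-T-", ]
  expect_equal(row$n, 8)
  expect_equal(row$ptau_median, 0.1)
  expect_equal(row$ptau_q1, 0.1)
  expect_equal(sum(tbl$n), 8)
})

test_that("staging csv output carries stages and positivity bits", {
  cohort <- generate_cohort(small_config(seed = 23L))
  staged <- stage_cohort(cohort, build_thresholds(cohort))
  path <- withr::local_tempfile(fileext = ".csv")
  write_staging_csv(staged, path)
  back <- utils::read.csv(path)
  expect_equal(nrow(back), nrow(staged))
  expect_true(all(c("braak_stage", "biological_stage", "braak1_pos",
                    "me_pos") %in% names(back)))
  expect_equal(as.character(back$biological_stage),
               as.character(staged$biological_stage))
})
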