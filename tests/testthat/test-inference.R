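test_that("bootstrap percentile CI behaves on degenerate and normal data", {
  ci <- bootstrap_ci(mean, rep(5, 20), B = 200, seed = 1)
  expect_equal(ci, c(5, 5))

  set.seed(3)
  for (i in 1:5) {
    x <- rnorm(60)
    ci <- bootstrap_ci(mean, x, B = 300, seed = i)
    expect_lte(ci[1], ci[2])
  }
})

test_that("bootstrap CI width matches the closed-form normal comparison", {
  # mean of n = 200 standard normal values: CI width ~ 2 * 1.96 / sqrt(200)
  expected <- 2 * qnorm(0.975) / sqrt(200)
  set.seed(12)
  widths <- vapply(1:8, function(i) {
    x <- rnorm(200)
    ci <- bootstrap_ci(mean, x, B = 1000, seed = 100 + i)
    ci[2] - ci[1]
  }, numeric(1))
  expect_lt(abs(mean(widths) - expected) / expected, 0.20)
})

test_that("bootstrap is deterministic under a seed and supports subsampling", {
  x <- rnorm(50)
  a <- bootstrap_ci(mean, x, B = 200, seed = 9)
  b <- bootstrap_ci(mean, x, B = 200, seed = 9)
  expect_identical(a, b)
  s <- bootstrap_ci(mean, x, B = 200, seed = 9, method = "subsample")
  expect_lte(s[1], s[2])
  # m-out-of-n without replacement widens the interval (m = n/2, unscaled)
  expect_gt(s[2] - s[1], (a[2] - a[1]) * 0.8)
})

test_that("bootstrap gives up when the statistic fails on too many replicates", {
  expect_error(
    bootstrap_ci(function(d) stop("no"), rnorm(10), B = 100, seed = 1),
    "failed"
  )
})

test_that("Spearman correlation matches rank formula values and flags constants", {
  expect_equal(spearman_cor(1:10, (1:10)^2, B = 0)$r, 1)
  expect_equal(spearman_cor(1:10, -(1:10), B = 0)$r, -1)
  # d^2 formula: 1 - 6*2/(4*15) = 0.8
  expect_equal(spearman_cor(1:4, c(1, 3, 2, 4), B = 0)$r, 0.8)
  expect_error(spearman_cor(rep(1, 5), 1:5, B = 0), "constant")
  ct <- spearman_cor(rnorm(30), rnorm(30), B = 200, seed = 2)
  expect_true(ct$ci_lo <= ct$r && ct$r <= ct$ci_hi)
})

test_that("DeLong comparison handles identical scores and hand-computed placements", {
  s <- c(0.2, 0.8, 0.4, 0.9)
  l <- c(FALSE, TRUE, FALSE, TRUE)
  same <- delong_compare(s, s, l)
  expect_equal(same$auc_diff, 0)
  expect_equal(same$p, 1)

  # 2 positives / 2 negatives, hand-computed placement values:
  # a: pos {0.8, 0.9} vs neg {0.2, 0.4}: placements pos = (1, 1), neg = (1, 1)
  # b: pos {0.9, 0.3} vs neg {0.2, 0.4}: placements pos = (1, 0.5),
  #    neg = (1, 0.5)
  a <- c(0.2, 0.8, 0.4, 0.9)
  b <- c(0.2, 0.9, 0.4, 0.3)
  cmp <- delong_compare(a, b, l)
  expect_equal(cmp$auc_a, 1)
  expect_equal(cmp$auc_b, 0.75)
  # S10 and S01 each contribute var(c(1, 0.5))/2 = 0.125/2; covariance with
  # the constant placements of model a is zero
  expect_equal(cmp$var_diff, 0.125 / 2 + 0.125 / 2)
  expect_equal(cmp$z, 0.25 / sqrt(0.125))
  expect_error(delong_compare(a, b[1:3], l), "paired")
})

test_that("DeLong agrees with an independent implementation on random data", {
  skip_if_not_installed("pROC")
  set.seed(21)
  for (i in 1:10) {
    n <- 60
    labels <- rep(c(TRUE, FALSE), each = n / 2)
    x <- rnorm(n) + labels
    y <- 0.5 * x + rnorm(n)
    ours <- delong_compare(x, y, labels)
    ref <- pROC::roc.test(
      pROC::roc(labels, x, quiet = TRUE, direction = "<"),
      pROC::roc(labels, y, quiet = TRUE, direction = "<"),
      method = "delong"
    )
    expect_equal(ours$p, unname(ref$p.value), tolerance = 1e-9)
    expect_equal(ours$auc_a, as.numeric(ref$estimate[1]), tolerance = 1e-12)
  }
})

test_that("logistic fit matches an independent Newton-Raphson oracle", {
  # overlapping classes: no separation, so the MLE is finite
  df <- data.frame(
    x1 = c(0.2, 1.5, 0.7, 2.2, 1.1, 0.4, 1.9, 2.8),
    x2 = c(1, 0, 1, 1, 0, 0, 1, 0),
    y = c(0, 1, 1, 1, 0, 0, 1, 0)
  )
  fit <- fit_logistic(df, y ~ x1 + x2)
  oracle <- logistic_newton(df[, c("x1", "x2")], df$y)
  expect_equal(unname(fit$coefficients), unname(oracle), tolerance = 1e-6)
  expect_true(fit$converged)

  # monotone-transform rank invariance for a single-feature model:
  # predicted probabilities preserve the AUC of the raw feature
  fit1 <- fit_logistic(df, y ~ x1)
  expect_equal(auc_rank(fit1$fitted, df$y), auc_rank(df$x1, df$y),
               tolerance = 1e-12)

  expect_error(fit_logistic(data.frame(x = 1:5, y = rep(1, 5)), y ~ x),
               "single class")

  sep <- data.frame(x = c(1, 2, 3, 10, 11, 12), y = rep(c(0, 1), each = 3))
  fsep <- fit_logistic(sep, y ~ x)
  expect_true(fsep$separation_flag)
})

test_that("Bonferroni adjustment caps at 1 and is monotone", {
  p <- c(0.001, 0.01, 0.04, 0.3)
  adj <- bonferroni(p)
  expect_equal(adj, pmin(1, 4 * p))
  expect_true(all(diff(adj[order(p)]) >= 0))
  expect_equal(bonferroni(0.5, m = 10), 1)
})

test_that("group comparison gates on Shapiro-Wilk and reports Tukey contrasts", {
  set.seed(8)
  norm_df <- data.frame(
    v = c(rnorm(30, 0), rnorm(30, 0.2), rnorm(30, 0.4)),
    g = rep(c("a", "b", "c"), each = 30)
  )
  gc1 <- compare_groups(norm_df, "v", "g")
  expect_equal(glance(gc1)$test, "anova")
  expect_true(glance(gc1)$normal_residuals)
  expect_equal(nrow(tidy(gc1)), 3)

  skew_df <- data.frame(
    v = c(rlnorm(40, 0, 1), rlnorm(40, 1, 1)),
    g = rep(c("a", "b"), each = 40)
  )
  gc2 <- compare_groups(skew_df, "v", "g")
  expect_equal(glance(gc2)$test, "kruskal-wallis")

  same <- data.frame(v = rep(c(1, 2, 3, 4), 2),
                     g = rep(c("a", "b"), each = 4))
  gc3 <- compare_groups(same, "v", "g")
  expect_lt(glance(gc3)$statistic, 1e-10)
  expect_true(all(tidy(gc3)$p_adj > 0.99))

  expect_error(compare_groups(data.frame(v = 1:4, g = c("a", "a", "a", "b")),
                              "v", "g"), "at least 3")
})

test_that("groups shifted by 1.5 pooled SD are detected at >= 90% rate", {
  set.seed(15)
  hits <- 0
  reps <- 400
  for (i in seq_len(reps)) {
    df <- data.frame(v = c(rnorm(15, 0, 1), rnorm(15, 1.5, 1)),
                     g = rep(c("a", "b"), each = 15))
    gc <- compare_groups(df, "v", "g")
    if (all(tidy(gc)$p_adj < 0.05)) hits <- hits + 1
  }
  expect_gte(hits / reps, 0.90)
})

test_that("chi-square on a diagonal 2x2 table reproduces the hand computation", {
  tab <- matrix(c(10, 0, 0, 10), nrow = 2)
  res <- chisq_compare(tab)
  expect_equal(res$statistic, 20)  # sum((O-E)^2/E) with E = 5 throughout
  expect_equal(res$df, 1)
  expect_lt(abs(res$p - 7.7e-6) / 7.7e-6, 0.05)
})

test_that("Cohen's d uses the pooled n-1 SD", {
  expect_equal(cohens_d(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(cohens_d(c(1, 2, 3), c(2, 3, 4)), -1)  # pooled SD 1
  expect_error(cohens_d(c(1, 1), c(1, 1)), "zero")
})

test_that("two-sample t-test power matches the noncentral-t reference", {
  expect_equal(power_two_sample(20, 0), 0.05, tolerance = 1e-12)
  expect_gt(power_two_sample(10000, 1.5), 0.9999)
  # the design condition: 15 per subgroup, d = 1.5 gives at least 90% power
  p15 <- power_two_sample(15, 1.5)
  expect_gte(p15, 0.90)
  expect_equal(p15,
               power.t.test(n = 15, delta = 1.5, sd = 1,
                            sig.level = 0.05)$power,
               tolerance = 1e-6)
  expect_error(power_two_sample(15, 1.5, alpha = 0), "alpha")
})
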