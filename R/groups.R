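#' Omnibus and pairwise comparison of a quantitative variable across groups
#'
#' Reproduces the standard biomarker-table workflow: residual normality is
#' assessed with a Shapiro-Wilk test at alpha = 0.05; normally distributed
#' residuals get a one-way ANOVA, otherwise a Kruskal-Wallis test; pairwise
#' contrasts use Tukey's Honest Significant Difference (family-wise error
#' rate 0.05), reported as adjusted p-values.
#'
#' @param data A data frame.
#' @param value Column name of the quantitative variable.
#' @param group Column name of the grouping factor; at least 2 groups with
#'   at least 3 values each.
#' @param alpha_normality Shapiro-Wilk alpha gating ANOVA vs Kruskal-Wallis.
#' @return A `group_comparison` list: `omnibus` (tibble with `test`,
#'   `statistic`, `p`, `shapiro_p`, `normal_residuals`) and `pairwise`
#'   (tibble of Tukey HSD contrasts with `estimate` and `p_adj`).
#' @export
compare_groups <- function(data, value, group, alpha_normality = 0.05) {
  v <- data[[value]]
  g <- factor(data[[group]])
  g <- droplevels(g)
  if (nlevels(g) < 2L) stop("need at least 2 groups", call. = FALSE)
  sizes <- table(g)
  if (any(sizes < 3L)) {
    stop("every group needs at least 3 values; smallest has ", min(sizes),
         call. = FALSE)
  }
  df <- data.frame(v = v, g = g)
  fit <- stats::aov(v ~ g, data = df)
  res <- stats::residuals(fit)
  # shapiro.test caps at n = 5000; subsample deterministically above that
  res_test <- if (length(res) > 5000) res[seq(1, length(res), length.out = 5000)] else res
  sw <- stats::shapiro.test(res_test)
  normal <- sw$p.value >= alpha_normality

  if (normal) {
    an <- summary(fit)[[1]]
    omnibus <- tibble::tibble(
      test = "anova", statistic = an$`F value`[1], p = an$`Pr(>F)`[1],
      shapiro_p = sw$p.value, normal_residuals = TRUE
    )
  } else {
    kw <- stats::kruskal.test(v ~ g, data = df)
    omnibus <- tibble::tibble(
      test = "kruskal-wallis", statistic = unname(kw$statistic),
      p = kw$p.value, shapiro_p = sw$p.value, normal_residuals = FALSE
    )
  }
  tk <- stats::TukeyHSD(fit, conf.level = 0.95)$g
  pairwise <- tibble::tibble(
    contrast = rownames(tk),
    estimate = tk[, "diff"],
    ci_lo = tk[, "lwr"],
    ci_hi = tk[, "upr"],
    p_adj = tk[, "p adj"]
  )
  structure(list(omnibus = omnibus, pairwise = pairwise),
            class = "group_comparison")
}

#' Chi-square test for categorical variables across groups
#'
#' Pearson chi-square on the contingency table of two categorical vectors,
#' without continuity correction.
#'
#' @param x,y Categorical vectors, or `x` may be a contingency table/matrix.
#' @return Tibble with `statistic`, `df`, `p`.
#' @export
chisq_compare <- function(x, y = NULL) {
  tab <- if (is.matrix(x) || is.table(x)) as.table(as.matrix(x)) else table(x, y)
  ct <- stats::chisq.test(tab, correct = FALSE)
  tibble::tibble(statistic = unname(ct$statistic),
                 df = unname(ct$parameter),
                 p = ct$p.value)
}

#' Cohen's d effect size for two samples
#'
#' Standardized mean difference `(mean(a) - mean(b)) / s_pooled`, with the
#' pooled SD using n - 1 weighting.
#'
#' @param a,b Numeric vectors, each with at least 2 values.
#' @return Cohen's d (signed).
#' @export
cohens_d <- function(a, b) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2)
  if (sp2 == 0) stop("pooled SD is zero; effect size undefined", call. = FALSE)
  (mean(a) - mean(b)) / sqrt(sp2)
}

#' Power of the two-sided two-sample t-test
#'
#' Exact power via the noncentral t distribution, for equal group sizes and a
#' standardized effect size (Cohen's d). At `effect_size = 0` the power
#' equals the type-I error rate `alpha`.
#'
#' @param n_per_group Per-group sample size (>= 2).
#' @param effect_size Standardized mean difference (>= 0).
#' @param alpha Two-sided significance level in (0, 1).
#' @return Power in `[0, 1]`.
#' @examples
#' power_two_sample(15, 1.5)  # the minimum-subgroup design condition
#' @export
power_two_sample <- function(n_per_group, effect_size, alpha = 0.05) {
  stopifnot(n_per_group >= 2, effect_size >= 0, alpha > 0, alpha < 1)
  df <- 2 * n_per_group - 2
  ncp <- effect_size * sqrt(n_per_group / 2)
  tc <- stats::qt(1 - alpha / 2, df)
  stats::pt(tc, df, ncp = ncp, lower.tail = FALSE) +
    stats::pt(-tc, df, ncp = ncp, lower.tail = TRUE)
}
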