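#' Percentile bootstrap confidence interval
#'
#' Resamples rows of `data` (paired resampling: whole rows, so paired
#' statistics stay paired), recomputes `statistic` on each replicate, and
#' returns the percentile interval of the replicate distribution. The default
#' is the conventional with-replacement bootstrap with B = 1000 replicates
#' and 95% coverage. A subsampling mode (`method = "subsample"`: m-out-of-n
#' without replacement, m = floor(n/2), no rescaling, hence approximate) is
#' available for sensitivity analyses.
#'
#' Replicates on which the statistic fails (e.g. a resample with a single
#' class) are redrawn up to 10 times each; if more than 10% of replicates
#' still fail, the interval is abandoned with an error.
#'
#' @param statistic Function of a data frame (or vector) returning a scalar.
#' @param data A data frame or vector to resample.
#' @param B Number of replicates (>= 100).
#' @param level Coverage level (default 0.95).
#' @param seed Optional integer seed making the interval reproducible.
#' @param method `"bootstrap"` (with replacement, default) or
#'   `"subsample"`.
#' @return Numeric vector `c(lo, hi)`.
#' @examples
#' bootstrap_ci(mean, rnorm(50), B = 200, seed = 1)
#' @export
bootstrap_ci <- function(statistic, data, B = 1000, level = 0.95,
                         seed = NULL, method = c("bootstrap", "subsample")) {
  method <- match.arg(method)
  stopifnot(B >= 100, level > 0, level < 1)
  is_df <- is.data.frame(data)
  n <- if (is_df) nrow(data) else length(data)
  if (n < 2L) stop("bootstrap needs at least 2 rows", call. = FALSE)
  if (!is.null(seed)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
  }
  m <- if (method == "subsample") max(2L, floor(n / 2)) else n
  draw <- function() {
    idx <- sample.int(n, m, replace = (method == "bootstrap"))
    if (is_df) data[idx, , drop = FALSE] else data[idx]
  }
  stats <- numeric(B)
  n_fail <- 0L
  for (b in seq_len(B)) {
    val <- NA_real_
    for (try in 1:10) {
      val <- tryCatch(statistic(draw()), error = function(e) NA_real_)
      if (is.finite(val)) break
    }
    if (!is.finite(val)) n_fail <- n_fail + 1L
    stats[b] <- val
  }
  if (n_fail > 0.10 * B) {
    stop("statistic failed on ", n_fail, " of ", B,
         " bootstrap replicates (limit 10%)", call. = FALSE)
  }
  alpha <- (1 - level) / 2
  unname(quantile(stats[is.finite(stats)], c(alpha, 1 - alpha), type = 7,
                  names = FALSE))
}

#' Spearman rank correlation with a bootstrap CI
#'
#' Computes the Spearman correlation (Pearson correlation of mid-ranks; ties
#' receive average ranks) and, optionally, a percentile bootstrap interval
#' over paired resamples.
#'
#' @param x,y Numeric vectors of equal length >= 3; neither may be constant.
#' @param B Bootstrap replicates (0 skips the CI).
#' @param level CI coverage.
#' @param seed Optional seed for the bootstrap.
#' @return A tibble with `r`, `ci_lo`, `ci_hi`, `n`.
#' @export
spearman_cor <- function(x, y, B = 1000, level = 0.95, seed = NULL) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (sd(x) == 0 || sd(y) == 0) {
    stop("rank correlation undefined for a constant vector", call. = FALSE)
  }
  r <- stats::cor(x, y, method = "spearman")
  ci <- c(NA_real_, NA_real_)
  if (B > 0) {
    ci <- bootstrap_ci(
      function(d) {
        if (sd(d$x) == 0 || sd(d$y) == 0) stop("constant resample")
        stats::cor(d$x, d$y, method = "spearman")
      },
      data.frame(x = x, y = y), B = B, level = level, seed = seed
    )
  }
  tibble::tibble(r = r, ci_lo = ci[1], ci_hi = ci[2], n = length(x))
}

# Placement values: for each case, the proportion of opposite-class cases it
# outranks (ties 1/2). Mean placement of positives equals the AUC.
delong_placements <- function(scores, labels) {
  labels <- as.logical(labels)
  xs <- scores[labels]   # positives
  ys <- scores[!labels]  # negatives
  v_pos <- vapply(xs, function(x) mean((x > ys) + 0.5 * (x == ys)), numeric(1))
  v_neg <- vapply(ys, function(y) mean((xs > y) + 0.5 * (xs == y)), numeric(1))
  list(v_pos = v_pos, v_neg = v_neg, auc = mean(v_pos))
}

#' DeLong test for two correlated AUCs
#'
#' Compares the AUCs of two score vectors measured on the same records (a
#' paired design) using the structural-components (placement-value)
#' formulation: the variance of the AUC difference combines the empirical
#' covariance matrices of the per-case placement values, and the difference
#' is referred to a two-sided normal. The degenerate case of identical AUCs
#' with zero variance returns p = 1.
#'
#' @param scores_a,scores_b Paired score vectors on identical records.
#' @param labels Binary truth labels; both classes present.
#' @return A tibble with `auc_a`, `auc_b`, `auc_diff`, `var_diff`, `z`, `p`.
#' @export
delong_compare <- function(scores_a, scores_b, labels) {
  if (length(scores_a) != length(scores_b) ||
      length(scores_a) != length(labels)) {
    stop("scores_a, scores_b and labels must be paired (equal length)",
         call. = FALSE)
  }
  labels <- as.logical(labels)
  m <- sum(labels)
  n <- sum(!labels)
  if (m == 0L || n == 0L) stop("both classes required", call. = FALSE)
  pa <- delong_placements(scores_a, labels)
  pb <- delong_placements(scores_b, labels)
  # 2x2 covariance matrices of placements for positives (S10) and
  # negatives (S01)
  s10 <- stats::cov(cbind(pa$v_pos, pb$v_pos))
  s01 <- stats::cov(cbind(pa$v_neg, pb$v_neg))
  s <- s10 / m + s01 / n
  var_diff <- s[1, 1] + s[2, 2] - 2 * s[1, 2]
  diff <- pa$auc - pb$auc
  if (var_diff <= 0) {
    z <- if (abs(diff) < .Machine$double.eps^0.5) 0 else sign(diff) * Inf
  } else {
    z <- diff / sqrt(var_diff)
  }
  p <- if (is.infinite(z)) 0 else 2 * pnorm(-abs(z))
  tibble::tibble(auc_a = pa$auc, auc_b = pb$auc, auc_diff = diff,
                 var_diff = var_diff, z = z, p = p)
}

#' Logistic model for predicted probability of an outcome
#'
#' Fits a maximum-likelihood logistic regression (iteratively reweighted
#' least squares via [stats::glm()], intercept always included) and returns
#' the in-sample predicted probabilities used as the composite score for
#' downstream ROC analysis. Complete or quasi-complete separation (detected
#' via the glm convergence warnings or exploding coefficients) is flagged
#' rather than silently accepted.
#'
#' @param data A data frame holding the features and labels.
#' @param formula Model formula, e.g. `abeta_pos ~ ptau217 + age + sex`.
#' @return A `logistic_fit` list: `coefficients`, `fitted` (predicted
#'   probabilities), `converged`, `separation_flag`, `n`, and the underlying
#'   `glm` object.
#' @export
fit_logistic <- function(data, formula) {
  mf <- stats::model.frame(formula, data = data)
  y <- stats::model.response(mf)
  if (length(unique(y)) < 2L) {
    stop("outcome has a single class; logistic fit undefined", call. = FALSE)
  }
  separation <- FALSE
  fit <- withCallingHandlers(
    stats::glm(formula, data = data, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-8, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        separation <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  if (any(abs(stats::coef(fit)[-1]) > 1e4, na.rm = TRUE)) separation <- TRUE
  structure(
    list(
      coefficients = stats::coef(fit),
      fitted = unname(stats::fitted(fit)),
      converged = fit$converged,
      separation_flag = separation,
      n = nrow(mf),
      glm = fit
    ),
    class = "logistic_fit"
  )
}

#' Bonferroni adjustment
#'
#' `min(1, m * p)` for a family of `m` tests; monotone in `p`.
#'
#' @param p Vector of raw p-values.
#' @param m Family size (default `length(p)`).
#' @return Adjusted p-values.
#' @export
bonferroni <- function(p, m = length(p)) {
  pmin(1, m * p)
}
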