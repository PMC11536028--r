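# Shared fixtures and independent oracles used across the suite.

# Small cohort for fast pipeline-level tests.
small_config <- function(seed = 11L, ...) {
  cohort_config(
    n_per_group = c(CU = 60, MCI = 40, dementia = 50),
    seed = seed,
    ...
  )
}

# Build a minimal hand-crafted cohort: every required region at `baseline`,
# with per-record overrides applied on top. Used to construct exactly
# controlled staging inputs.
manual_cohort <- function(n, baseline = 1.0, centiloid = 0, group = "CU",
                          ptau217 = 0.1) {
  regions <- required_regions()
  suvr <- matrix(baseline, nrow = n, ncol = length(regions),
                 dimnames = list(NULL, paste0("suvr_", regions)))
  tibble::tibble(
    id = sprintf("M%03d", seq_len(n)),
    group = factor(rep_len(group, n), levels = c("CU", "MCI", "dementia")),
    age = 75,
    sex = factor(rep_len("female", n), levels = c("male", "female")),
    apoe4 = FALSE,
    centiloid = rep_len(centiloid, n),
    ptau217 = rep_len(ptau217, n)
  ) |>
    dplyr::bind_cols(tibble::as_tibble(suvr))
}

# Set all regions of the named composites to `value` for record `i`.
set_composite_regions <- function(cohort, i, composites, value) {
  defs <- composite_definitions()
  for (nm in composites) {
    for (r in defs[[nm]]$regions) {
      cohort[[paste0("suvr_", r)]][i] <- value
    }
  }
  cohort
}

# Fixed threshold set for staging tests: every tau cutoff at `cut`.
fixed_thresholds <- function(cut = 1.5, cl_cutoff = 25, te_high = 2.68) {
  comps <- names(composite_definitions())
  structure(
    list(
      cl_cutoff = cl_cutoff,
      tau_cutoffs = stats::setNames(rep(cut, length(comps)), comps),
      te_high_cutoff = te_high,
      tau_method = "mean_plus_k_sd", k = 2.5, p = NULL,
      provenance = list(n_reference = NA_integer_, n_part_excluded = 0L,
                        te_high_mode = "fixed")
    ),
    class = "threshold_set"
  )
}

# Independent brute-force AUC: mean over all (pos, neg) pairs of the
# concordance indicator, ties counted 1/2.
auc_pairs <- function(scores, labels) {
  labels <- as.logical(labels)
  xs <- scores[labels]
  ys <- scores[!labels]
  tot <- 0
  for (x in xs) tot <- tot + sum(x > ys) + 0.5 * sum(x == ys)
  tot / (length(xs) * length(ys))
}

# Trapezoidal area under the empirical ROC trace.
auc_trapezoid <- function(roc) {
  fpr <- rev(1 - roc$trace$spec)
  tpr <- rev(roc$trace$sens)
  fpr <- c(fpr, 1); tpr <- c(tpr, 1)  # close the curve at (1, 1)
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

# Closed-form AUC when both classes are log-normal with common log-sd.
lognormal_auc <- function(median_neg, median_pos, sdlog) {
  pnorm((log(median_pos) - log(median_neg)) / (sdlog * sqrt(2)))
}

# Brute-force Braak rule: largest k with bits 1..k true and k+1..6 false,
# else Atypical.
braak_oracle <- function(bits) {
  for (k in 6:0) {
    if (all(bits[seq_len(k)]) && !any(bits[seq_len(6 - k) + k])) {
      return(c("0", "I", "II", "III", "IV", "V", "VI")[k + 1L])
    }
  }
  "Atypical"
}

# Independent Newton-Raphson logistic regression with step halving
# (oracle for fit_logistic).
logistic_newton <- function(X, y, tol = 1e-12, maxit = 200) {
  X <- cbind(1, as.matrix(X))
  loglik <- function(beta) {
    eta <- drop(X %*% beta)
    sum(y * eta - log1p(exp(eta)))
  }
  beta <- rep(0, ncol(X))
  ll <- loglik(beta)
  for (i in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    p <- 1 / (1 + exp(-eta))
    W <- p * (1 - p)
    g <- crossprod(X, y - p)
    H <- crossprod(X * W, X)
    step <- drop(solve(H, g))
    # halve until the log-likelihood does not decrease
    lambda <- 1
    repeat {
      cand <- beta + lambda * step
      if (loglik(cand) >= ll - 1e-12 || lambda < 1e-8) break
      lambda <- lambda / 2
    }
    beta <- beta + lambda * step
    ll_new <- loglik(beta)
    if (max(abs(lambda * step)) < tol) break
    ll <- ll_new
  }
  drop(beta)
}
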