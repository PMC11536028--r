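---
title: "Methods: plasma pTau217 diagnostic accuracy and PET-based staging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: plasma pTau217 diagnostic accuracy and PET-based staging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## What this package models

Plasma pTau217 (tau phosphorylated at threonine 217, measured in pg/ml) is a
blood biomarker of Alzheimer's disease pathology. In a memory-clinic research
setting its clinical value rests on two questions this package answers with
reusable, tested components:

1. **Detection** -- how well does a single blood value predict amyloid-PET
   positivity (Centiloid scale) and tau-PET positivity (SUVR in composite
   regions of interest)?
2. **Staging** -- does the blood value track the topographic extent and
   magnitude of tau aggregation, summarized as PET-based Braak stages and as
   the four biological AD stages (Initial, Early, Intermediate, Advanced)?

Because the underlying patient-level data of such studies are not publicly
deposited, the package pairs the analysis pipeline with a calibrated
synthetic cohort generator, so every downstream component is exercised
end-to-end against known ground truth.

```{r, message = FALSE}
library(ptau217)
cohort <- generate_cohort(cohort_config(seed = 42))
thresholds <- build_thresholds(cohort)
staged <- stage_cohort(cohort, thresholds)
stage_table(staged)
```

## Composite ROIs and positivity thresholds

Tau PET SUVR is quantified in ten built-in composites: mesial temporal
(`Me`: entorhinal, hippocampus, parahippocampal, amygdala), temporoparietal
(`Te`), rest-of-neocortex (`R`), meta temporal (`MetaT`), and the six
Braak-stage composites from the Desikan-Killiany parcellation. Composites
are unweighted means of their regional SUVR by default; whether clinical
pipelines volume-weight these means is rarely reported, so equal weighting
is the documented default and per-region weights are available for sites
that need volume weighting. Region names are normalized (lower case,
underscores) before lookup, and the parahippocampal gyrus is a single
canonical region even though composite conventions name it inconsistently.

Positivity rules:

* **Amyloid**: Centiloid >= 25 (the stated inequality); sensitivity
  analyses sweep the cutoff across 10-50 CL.
* **Tau**: composite SUVR strictly greater than a cutoff derived from the
  amyloid-negative cognitively unimpaired (CU) reference stratum, either
  mean + 2.5 SD (sample SD, n - 1; the primary rule) or the 95th
  percentile. Percentiles use linear interpolation between order statistics
  (type 7); the choice of convention is documented because published
  analyses almost never state one. For reference strata of realistic size
  the two differ by far less than between-subject variability, and for
  normal reference data mean + 2.5 SD sits at the 99.38th percentile.
* **High tau**: the boundary between moderate and high temporoparietal tau
  is the upper quartile of Te SUVR among amyloid-positive MCI/dementia
  participants. The fixed literature value 2.68 SUVR (derived on a larger
  imaging cohort than a single study sample) is the default; re-derivation
  from the analyzed cohort is available (`te_high = "derive"`). The
  boundary is floored at the Te positivity cutoff so the threshold set can
  never be internally inconsistent.

An optional stand-in rule for primary age-related tauopathy (PART) removes
amyloid-negative records with mesial-temporal tau above a provisional Me
cutoff from the Braak-composite reference stratum and recomputes those
cutoffs once. Published criteria for PART exclusion are typically unstated;
this rule is therefore off by default and clearly labelled as this
package's operationalization, not a published definition.

## Staging rules

**Braak staging.** A record's stage is the "latest" positive Braak
composite given all earlier composites are positive: an all-negative
profile is stage 0, a positive prefix of length k is stage k, and any
out-of-order profile is `Atypical`. The rule is a total function on the 64
possible positivity vectors; exactly seven are non-atypical, and the test
suite checks the implementation against an independent brute-force rule on
all 64. Stages are grouped I-II / III-IV / V-VI for reporting (stage II is
rare in practice) and dichotomized low (0-III) vs high (IV-VI) for ROC
analyses.

**Biological staging.** Combining amyloid status with tau extent and
magnitude: `A-T-` (amyloid-negative, tau-negative in Me/Te/R), `Initial`
(A+, all tau negative), `Early` (A+, tau limited to the mesial temporal
lobe), `Intermediate` (A+, Te positive at or below the high-tau boundary),
`Advanced` (A+, Te above the boundary). Two deliberate choices close gaps
the published criteria leave open: "moderate tau" is operationalized as
Te-positive regardless of Me/R status, because Te drives the
moderate/advanced split in the trial methodology this staging follows; and
amyloid-negative records with any tau positivity, as well as A+ records
with R-positive but Te-negative tau, are `Atypical` rather than forced into
a stage. Holding everything else fixed, increasing Te SUVR can never move a
record to an earlier stage, and both staging schemes partition any cohort
exactly.

## Diagnostic-accuracy statistics

* **ROC/AUC.** Candidate thresholds are the unique observed scores plus a
  sentinel above the maximum; the classification rule is score >= threshold
  so chosen cutoffs land on observed concentrations. AUC uses the rank
  (Mann-Whitney) statistic with ties counted 1/2, which equals the
  trapezoidal area exactly; the suite asserts the equality and invariance
  under strictly increasing transforms on 1000 randomized instances.
* **Operating points.** Youden's J = sens + spec - 1 is maximized over the
  candidate set with ties broken toward the lowest threshold (higher
  sensitivity -- the right bias for a screening assay); tie detection uses
  integer-scaled counts, immune to floating-point rounding. Fixed-target
  operating points take the largest threshold meeting a sensitivity target
  or the smallest meeting a specificity target, maximizing the
  complementary metric subject to the constraint. PPV/NPV are raw,
  never prevalence-adjusted; undefined ratios are reported missing, not 0.
* **Two-threshold triage.** A lower cutoff at 95% (or 90%) sensitivity and
  an upper cutoff at 90% specificity split the cohort into Low /
  Indeterminate / High zones; boundary values are Indeterminate. Agreement
  with amyloid-PET status is summarized only over the Low and High zones.
* **Bootstrap CIs.** Percentile intervals from B = 1000 paired
  row-resamples with replacement. Published wording sometimes says
  "bootstrap without replacement", which describes no standard bootstrap;
  the conventional with-replacement scheme is the default here, and an
  m-out-of-n subsampling mode (m = n/2, without replacement, unscaled and
  documented as approximate) is available for sensitivity analyses.
  Degenerate replicates (single-class resamples) are redrawn up to a cap;
  systematic failure aborts rather than silently biasing the interval.
* **DeLong comparisons.** Correlated AUCs on paired designs are compared
  via the structural-components (placement-value) formulation with a
  two-sided normal reference; zero-variance, zero-difference degenerates
  return p = 1. The suite calibrates the test's size under a simulated null
  (2000 replications) and cross-checks p-values against an independent
  implementation.
* **Group comparisons.** Shapiro-Wilk on residuals (alpha 0.05) gates
  one-way ANOVA vs Kruskal-Wallis; pairwise contrasts use Tukey HSD;
  categorical contrasts use chi-square without continuity correction;
  Bonferroni handles families of correlation/DeLong tests. These standard
  fits are delegated to base R; the package adds the orchestration and the
  reporting surface.
* **Power.** The two-sample power at the design condition (15 per
  subgroup, effect size 1.5 SD) is computed from the noncentral t
  distribution and verified by simulation; it comfortably exceeds the 90%
  design requirement.

## The synthetic cohort generator

The generator is hierarchical -- clinical group, then amyloid status, then
biological stage, then measurements -- so every record carries truth labels
that recovery tests can condition on. Defaults encode the published study
conditions: group sizes 156/100/132 (CU/MCI/dementia), amyloid prevalence
0.40/0.69/0.89, and stage-wise pTau217 medians 0.1/0.2/0.4/0.6/0.9 pg/ml.
Where the published tables give only medians and IQRs, distributional
families are modeling decisions, chosen once:

* **pTau217** is log-normal around the stage median (log-SD 0.45, chosen to
  match the printed asymmetric IQRs); concentrations are positive and
  right-skewed, so a log-normal is the natural minimal model.
* **Centiloid** is a two-component mixture: amyloid-negative records draw
  from a normal centred near 0 (per-group location matching the printed
  medians, SD 6, truncated below -10 CL), amyloid-positive records from
  25 + a log-normal whose median matches the printed group medians
  (79-113 CL).
* **Tau SUVR** profiles start from baseline noise (mean 1.0, SD 0.06 per
  region) and add a stage-scaled elevation to every region in Braak
  composites 1..extent, where the extent is drawn per stage (Early: I-III,
  Intermediate: IV-V, Advanced: V-VI) and the elevation magnitude (0.9 /
  0.9 / 2.4 SUVR with 12% log-normal jitter) is set so Early records are
  Te-negative, Intermediate records land between the Te cutoff and 2.68,
  and Advanced records exceed 2.68.
* **Atypical profiles** are constructed by resetting one interior Braak
  composite of a tau-positive record to baseline while leaving later
  composites elevated -- the simplest construction violating prefix order.
  The rate (default 0.08) applies to records with tau spread beyond
  Braak I, since a stage-I-only profile cannot be out of order.
* **Covariates** (age, sex, APOE e4) are drawn per (group, amyloid) cell
  from the printed demographics, which gives the base covariate model a
  realistic amyloid association.

Randomness comes from a single seeded stream with a fixed, vectorized draw
order, so one seed yields one bit-identical cohort; per-record sub-streams
were considered and rejected as machinery without benefit at this scale.

What the generator does **not** emulate: longitudinal change, assay
measurement error beyond the log-normal spread, PET spatial correlation
between neighbouring regions, enrollment selection effects, and medical
comorbidities (e.g. renal function) that shift pTau levels in real
populations. Passing tests therefore demonstrate the correctness and
calibration of the pipeline, not the clinical performance of the assay on
any real population; the published headline numbers (AUC 0.93/0.94,
Spearman r 0.76/0.78, 17.8% indeterminate, 92% correct classification)
serve as plausibility anchors that synthetic cohorts approach but are not
expected to reproduce exactly.

## Numerical choices and degenerate inputs

* Percentiles and quartiles: type-7 linear interpolation throughout.
* Tau positivity: strictly greater than the cutoff; a value exactly at the
  cutoff is negative. Amyloid positivity: greater than or equal to 25 CL.
* Reported prevalences are rounded half away from zero to integers.
* Zero-denominator metrics (PPV with no predicted positives, agreement in
  an empty zone) are missing values, never zeros.
* Single-class label vectors are errors for ROC and logistic fits;
  logistic separation is flagged on the fitted object.
* Empty calibration strata are flagged rows, not crashes; strata under 5
  records are flagged as unstable.
* Test problem sizes (e.g. 2000 replications for the DeLong null, 500
  replications at n = 300 for bootstrap coverage, pooled five-seed cohorts
  for generator calibration) were chosen to keep Monte-Carlo error well
  inside the asserted bands while the whole suite stays fast enough to run
  routinely.

## Known limitations

* The Braak composite definitions follow one published transcription of
  the Desikan-Killiany groupings; sites using different parcellations can
  load custom composites but must then re-derive thresholds.
* The PART stand-in rule is a simple outlier screen, not a validated
  clinical definition.
* The m-out-of-n subsampling mode deliberately omits the rescaling needed
  for asymptotically correct intervals; it exists to mirror a published
  description, not as a recommended estimator.
* Prevalence-unadjusted PPV/NPV transfer poorly across populations with
  different amyloid prevalence; this is a property of the statistic, kept
  intentionally.
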