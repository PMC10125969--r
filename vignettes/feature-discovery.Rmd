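---
title: "Discovering machine-learned histologic features for nodal metastasis prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering machine-learned histologic features for nodal metastasis prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem and the model

In colorectal cancer, the presence of lymph-node metastasis (LNM)
separates stage II from stage III disease and drives the adjuvant-therapy
decision, yet it is determined only after surgery. The question this
package operationalizes is whether the primary tumor's histology, as seen
by a generic image model, carries signal for LNM *beyond* what the
standard clinicopathologic variables (age group, sex, tumor grade,
T-category, lymphatic and venous invasion) already explain.

The unit of analysis is a *case*: a bag of patch embedding vectors
(fixed-length outputs of a pretrained CNN applied to tissue tiles from the
tumor region) plus the case-level covariates and the binary LNM label.
The pipeline is:

1. **Feature generation.** Sample up to 64 patches per training case,
   pool them, and fit k-means with `K` clusters on the embeddings. Each
   cluster is a candidate "machine-learned feature".
2. **Quantitation.** Run *all* patches of a case through the fitted
   model and record the fraction assigned to each cluster — a length-`K`
   simplex vector. A case's value for feature `k` is its fraction of
   cluster-`k` patches.
3. **Selection.** Greedy forward selection over the candidate fractions:
   at each step, refit a logistic model and add the candidate that most
   increases training-set AUROC. Crucially, in the primary (controlled)
   mode the six baseline covariates stay in the model at every step, so a
   candidate is only rewarded for signal the covariates do not already
   carry. The uncontrolled variant (ML features only) is retained as a
   negative control: it tends to rediscover covariate-redundant features
   that add no external value.
4. **Evaluation.** Three complementary views on held-out cases:
   a nested-model likelihood-ratio test (covariates vs covariates +
   selected fractions, both fit on the evaluation set, chi-square with
   `df` = number of added features); multivariable odds ratios with Wald
   intervals; and the predictive AUROC gain of models trained on the
   training split, with paired case-level bootstrap intervals.
5. **Survival.** A logistic risk score trained on the selected fractions
   alone, thresholded at the median score of the development cohort's
   most recent five accrual years, stratifies node-negative and
   node-positive cases into low/high risk groups compared by
   Kaplan-Meier curves and log-rank tests.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `K_grid` | 10, 25, 50, 100, 200 | candidate cluster counts for the tune-split grid |
| `K` | 200 | cluster count when the grid is skipped |
| `n_select` | 5 | machine-learned features in the final model |
| `patches_per_case` | 64 | per-case sample size for k-means fitting |
| `n_boot` | 1000 | bootstrap resamples (percentile CIs) |
| `n_restarts` | 10 | k-means++ restarts |
| `controlled` | TRUE | covariates held in the model during selection |

`K = 200` with 5 selected features is the reference configuration; the
grid over `K` and 1-10 features, scored by tune-split AUROC of the
combined model, is how that configuration is chosen when
`run_grid = TRUE`. Diminishing returns beyond the true number of
informative clusters show up as a plateau in the tune AUROC.

## What the synthetic cohorts emulate — and what they do not

No patient-level data ships with the package; `generate_cohort()` builds
cohorts with the statistical structure the pipeline assumes:

* embeddings are drawn from a Gaussian mixture whose per-case component
  proportions follow a Dirichlet (concentration 1 by default — uniform
  over the simplex);
* a chosen subset of components is *informative*: their true proportions
  enter the LNM log-odds with configurable coefficients;
* covariates are drawn from configurable categorical marginals (uniform
  by default over 4 age bins, 2 sexes, 3 grades, 3 T-categories, binary
  L and V) and contribute their own log-odds effects;
* `covariate_component_coupling` can tie component proportions to
  covariate levels, creating the redundancy that controlled selection is
  supposed to reject;
* an optional batch effect shifts all embeddings of "batch 1" cases
  along a fixed direction, and `batch_label_logodds` can correlate batch
  membership with the label — an in-silico analog of a scan-date
  confound, where a model can score label-negative cases differently by
  batch for reasons unrelated to biology (`batch_confound_check()` tests
  exactly this contrast on label-negative cases only);
* survival is exponential with log-hazard proportional to the same
  linear score that generates the label, independently exponentially
  censored (administrative cutoff optional) — the simplest model that
  exercises Kaplan-Meier estimation and log-rank testing.

What passing tests on these cohorts shows is that the *machinery* is
correct and calibrated: selection finds planted signal, the LRT rejects
at its nominal rate when there is none, intervals cover. What they do not
show is anything about real embedding distributions: CNN embeddings of
tissue are not a spherical Gaussian mixture, real cluster fractions are
not Dirichlet, and real covariate-histology dependence is richer than a
linear coupling. The Gaussian-mixture assumption is a stand-in chosen for
testability, not a claim about pathology data.

The reference planted scenario (`planted_cohort_config()`) uses 50
components in 16 dimensions with three informative components. Its
effect size (70 per unit fraction) was calibrated by pilot simulation so
that each planted cluster's fraction has a univariable AUROC near 0.65
at 800 cases — strong enough that recovery is expected, weak enough that
selection is non-trivial — and its component separation (centroid scale
6 at unit patch noise) was calibrated so k-means recovers the true
components almost always. The intercept offsets the mean covariate and
component contributions to hold prevalence near 0.45.

## Numerical choices

* **k-means.** Lloyd iterations with greedy k-means++ seeding
  (`2 + floor(log K)` candidate points per step, the refinement
  scikit-learn also uses; with 50+ well-separated clusters,
  single-candidate seeding routinely merges components). 10 restarts by
  default, best inertia kept; convergence when the relative inertia
  improvement drops below `1e-4` (300 iterations cap); empty clusters
  are re-seeded at the point farthest from its center. The per-iteration
  inertia trace of the winning restart is retained — it must be
  non-increasing, and the test suite asserts that.
* **Assignment ties** go to the lowest cluster id; **selection ties**
  (equal AUROC within `1e-12`) go to the lowest candidate id — both for
  determinism.
* **Sampling** is without replacement with an exhaustion fallback: a
  case with fewer than 64 patches contributes all of them once, never
  duplicated, so small cases are not over-weighted.
* **Quantitation** uses all patches of a case, not the fitting sample; a
  case with zero patches is invalid input, not a zero vector.
* **Logistic fits** are unpenalized maximum likelihood (IRLS, deviance
  tolerance `1e-8`); covariance is the inverse observed information.
  Complete separation is flagged (`converged = FALSE`) instead of
  returning divergent estimates; during selection such candidate fits
  are skipped and logged. Coefficients on fraction-scale features are
  legitimately large (a fraction lives on [0, 1] and typical values are
  ~1/K), so separation is detected from boundary fitted probabilities,
  never from coefficient magnitude. Exactly collinear columns are
  reported with `NA` coefficients and `NA` Wald columns, as `glm` does.
* **ML fractions enter the design raw** (no standardization): the
  reported odds ratios are per unit fraction. This is a labeled choice —
  per-SD scaling would be equally defensible, and nothing downstream
  depends on it.
* **Reference levels** are age <60, male, G1, the lowest T-category
  present in the fitting data, L0, V0. Levels absent from the fitting
  data are dropped from the layout and recorded, so an external cohort
  with an extra T-category level fails loudly at encode time rather than
  silently re-aligning columns.
* **Operating point**: thresholds are scanned at midpoints between
  consecutive distinct scores (plus an all-positive sentinel), the
  harmonic mean of sensitivity and specificity is maximized, ties go to
  the lower threshold, and PPV/NPV are `NA` when undefined.
* **Bootstrap**: case-level resampling, jointly for both score vectors,
  percentile 2.5/97.5 limits; single-class resamples are redrawn and
  counted. Resampling is not stratified by label — the redraw rule makes
  stratification unnecessary at these prevalences.
* **Kaplan-Meier / log-rank** use the survival package (Greenwood
  variance, log-log interval transform; deaths precede censorings at
  tied times). Five-year survival reads the step function at the
  horizon; when a group's follow-up ends earlier, the last step value is
  reported and the group is flagged.

## Design decisions where the procedure was genuinely open

* **Which AUROC drives the greedy step.** Training-split AUROC drives
  each step; the tune split is reserved for choosing `(K, n)`. Folding
  tune performance into the step criterion would leak the model-choice
  data into feature construction.
* **Risk-score target.** The survival risk model is trained on the
  selected fractions against LNM by default, with a disease-specific
  death target available (`target = "dss_event"`). Both are legitimate
  anchors for risk stratification; the package exposes the choice
  instead of hard-wiring one.
* **Threshold boundary.** Cases with score exactly at the median go to
  the high-risk group (`score >= threshold`).
* **Split hygiene.** Split assignments live in the covariate table and
  are never inferred; the predictive evaluation refuses overlapping
  train/eval case ids outright. The analytic evaluations (LRT, odds
  ratios) are fit on the evaluation set by design — they measure
  association, not transferable prediction — and are exposed as separate
  functions so the two cannot be confused.

## Calibration study sizes

The null-calibration checks in the test suite and acceptance script use
a no-signal cohort of 2000 cases (30 patches each, K = 25, 5 tested
features) with labels redrawn per replicate from the covariate-only
truth model, and the tested 5-feature subset rotated across replicates.
Two considerations fix these sizes. First, the chi-square reference for
the likelihood-ratio test is asymptotic: with ~16 parameters, its actual
size at 400 cases is about 0.06 even for a textbook glm with no
package code involved, and approaches 0.05 only near 2000 cases — so a
small-n check would measure the chi-square approximation, not the
implementation. Second, the size *conditional on one fixed noise-feature
design* varies from design to design; rotating the subset measures the
marginal level, which is the quantity with a nominal value. For the
bootstrap delta interval, the null check uses a 1600/400 train/eval
split: fitting five noise features costs a small but systematic amount
of evaluation AUROC, and with an evaluation set as large as the training
set that real bias — not interval mis-calibration — dominates the paired
sampling noise.

## Known limitations

* Embeddings are consumed as given; nothing upstream (tumor detection,
  patch extraction, stain handling) is modeled.
* The survival analysis is descriptive risk stratification: no Cox
  modeling, no competing risks, no treatment adjustment.
* No multiple-testing correction is applied across evaluation sets.
* Percentile bootstrap intervals are first-order; DeLong variance
  estimates for AUROC are deliberately out of scope.
* The uncontrolled selection mode exists to demonstrate a failure mode;
  its output should not be used as a model.
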