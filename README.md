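# histofeat

Machine-learned histologic features for lymph-node metastasis prediction.

In colorectal cancer, nodal metastasis (LNM) separates stage II from
stage III and drives the adjuvant-chemotherapy decision, but it is only
known after surgery. `histofeat` asks whether the primary tumor's
histology — seen through patch embedding vectors from a pretrained CNN —
predicts LNM *beyond* the six baseline clinicopathologic variables (age
group, sex, grade, T-category, lymphatic and venous invasion). It is
aimed at computational-pathology researchers who have per-case bags of
patch embeddings plus a clinical covariate table, and at methodologists
who want a fully testable reference implementation of the
covariate-controlled feature-discovery recipe.

## The method

For a case with patches assigned to `K` k-means clusters fitted on
training-set embeddings, the *cluster quantitation vector*
`q = (q_1, ..., q_K)` holds the fraction of the case's patches in each
cluster (`q_k >= 0`, `sum q_k = 1`). Candidate feature `k` is `q_k`.
Selection is greedy and covariate-controlled: starting from the logistic
model

```
logit P(LNM) = b0 + b' x_clin
```

the candidate `q_k` maximizing training AUROC of the refit model
`logit P(LNM) = b0 + b' x_clin + g q_k (+ previously selected)` is added,
for `n` steps; `(K, n)` are chosen on a tune split (reference
configuration `K = 200`, `n = 5`, 64 sampled patches per case). Selected
features are then judged on held-out cases three ways:

* **Likelihood-ratio test**: covariates-only vs covariates + fractions,
  both fit on the evaluation set; `X2 = 2 (l1 - l0)` on `n` df.
* **Odds ratios**: multivariable Wald ORs per unit fraction, with
  `1.00 (reference)` rows for reference covariate levels.
* **Predictive AUROC gain**: clinical, clinical+ML and ML-only models
  trained on the training split, scored on the evaluation split, with
  paired case-level bootstrap 95% CIs for each AUROC and the delta.

A logistic risk score on the selected fractions alone, thresholded at
the median score of the development cohort's most recent five accrual
years, stratifies node-negative and node-positive cases into risk groups
compared with Kaplan-Meier curves and log-rank tests. A batch-confound
check compares scores across batches among label-negative cases only —
the signature of a scan-date-style artifact.

Everything runs end to end on synthetic cohorts from the bundled
generator (`generate_cohort()`), which plants informative mixture
components, covariate effects and coupling, optional batch shifts, and
exponential survival tied to the same linear score.

## Worked example

```r
library(histofeat)

co     <- generate_cohort(planted_cohort_config(n_cases = 400, seed = 7))
model  <- fit_clusters(sample_patches(co$embeddings, 16, seed = 7),
                       K = 50, seed = 7, n_restarts = 5)
quants <- quantitate_cases(model, co$embeddings)

train <- dplyr::filter(co$cases, split == "train")
val   <- dplyr::filter(co$cases, split == "validation")

(sel <- greedy_forward_select(train, quants, 1:50, n_select = 5))
#> <selection_result> controlled, K = 50
#> # A tibble: 5 × 4
#>    step cluster_id train_auroc train_loglik
#>   <int>      <int>       <dbl>        <dbl>
#> 1     1          4       0.743        -139.
#> 2     2         44       0.802        -125.
#> 3     3         33       0.852        -111.
#> 4     4         28       0.859        -108.
#> 5     5         11       0.870        -105.

likelihood_ratio_test(val, quants, sel$selected_ids)
#> Likelihood-ratio test: chi-square = 25.7672, df = 5, p = 9.9e-05

predictive_evaluation(train, val, quants, sel$selected_ids,
                      n_boot = 1000, seed = 7)
#> AUROC for LNM prediction (bootstrap 95% CI)
#>   Clinical       0.638 [0.519, 0.751]
#>   Clinical + ML  0.842 [0.753, 0.918]
#>   ML only        0.820 [0.724, 0.901]
#>   Delta          0.204 [0.086, 0.331]
```

Reading the output: each greedy step adds the cluster whose fraction
most improves training AUROC with the covariates held in the model; the
training AUROC trace is non-decreasing by construction. On the held-out
validation split the likelihood-ratio test rejects the covariates-only
model decisively (the generator plants three informative clusters), and
the combined model gains 0.204 AUROC over the clinical baseline, with a
bootstrap interval excluding zero. On a null cohort (no informative
components) the same delta interval covers zero about 95% of the time.

`run_pipeline()` chains simulate → cluster → select → evaluate →
survival and writes `report.txt`, odds-ratio/selection/KM tables and a
run manifest; `histofeat_cli()` (or `inst/cli/histofeat.R`) exposes the
same steps as shell subcommands. `tidy()`, `glance()` and `autoplot()`
methods cover the fitted objects.

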