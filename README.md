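# morphoclass

Case–case classification of tremor disorders from regional MRI
morphometry, for neuroimaging statisticians working with small cohorts.
The package targets the common rare-disease setting — two diagnostic
groups of a dozen-odd patients each (orthostatic tremor vs essential
tremor being the motivating contrast), a few hundred regional features,
and clinical covariates that must be adjusted for — and turns the whole
analysis into a tested, seeded, reproducible pipeline.

## What it computes

Starting from FreeSurfer-style regional statistics (or any assembled
subjects × features matrix) and a covariates table, the pipeline runs:

1. **Feature construction.** Per cortical region and hemisphere: grey
   volume, mean cortical thickness, and *roughness* — the within-region
   standard deviation of cortical thickness, a proxy for non-uniform
   thinning. Per subcortical structure: volume normalized by total
   intracranial volume (ICV) and by total grey matter (GM). Plus raw ICV.
   The default catalog has 34 × 2 × 3 + 38 × 2 + 1 = 281 features.
2. **ANCOVA screening.** Per feature, the group contrast adjusted for
   age, sex, education, and tremor duration; the partial F for the group
   term (df₁ = 1, df₂ = n − 6, i.e. F(1, 23) at n = 29) with effect size
   η²ₚ = F·df₁ / (F·df₁ + df₂). Screening at α = 0.05, uncorrected (a
   pre-filter, not a confirmatory family).
3. **IGR ranking.** Each screened feature scored by the information gain
   ratio of its best binary midpoint split (entropies in bits),
   IGR = IG/SI ∈ [0, 1], sorted descending.
4. **Greedy forward wrapper.** Starting from the top-ranked feature,
   each next-ranked feature is kept iff 10-fold cross-validated accuracy
   of a linear SVM (frozen stratified fold plan, features z-scored per
   training fold) is equal or higher than the current best.
5. **Evaluation.** Hard-margin linear-separability report (margin
   2/‖w‖), an exhaustive subset-search oracle, scatter-matrix figures,
   and subgroup re-runs (e.g. primary cases vs cases with mild
   parkinsonian signs) on identical machinery.

A synthetic cohort generator (`synthetic_spec()`, `generate_cohort()`,
`make_separable_cohort()`) emulates the cohort structure — group sizes
14/15, realistic covariate distributions, planted standardized effects,
optional covariate leakage — so calibration, power, and null behaviour of
every stage are tested, not assumed.

## Worked example

```r
library(morphoclass)

spec   <- synthetic_spec(feature_catalog = simple_catalog(20), seed = 42)
cohort <- make_separable_cohort(spec, k_informative = 2, margin = 5)

screen <- screen_features(cohort$table, cohort$covariates, alpha = 0.05)
screen[, c("feature_id", "f_stat", "df2", "p_value", "partial_eta2")]
#>   feature_id f_stat df2  p_value partial_eta2
#> 1        f02    439  23 1.75e-16        0.950
#> 2        f01    256  23 5.85e-14        0.918

y       <- cohort$covariates$group
X       <- cohort$table$values[, screen$feature_id, drop = FALSE]
ranking <- rank_features(X, y)
plan    <- cv_plan(y, n_folds = 10, stratified = TRUE, seed = 42)
greedy_wrapper_select(ranking, X, y, plan)
#> <selection_trace> 2 steps, 2 features kept, final CV accuracy 1.000
#>   subset: f01, f02

linear_separation(c("f01", "f02"), X, y)
#> <separation_report> {f01, f02}: separable, margin 2.1013
```

Reading: of 20 features, exactly the two planted informative ones survive
the covariate-adjusted screen (F(1, 23) = 439 and 256, η²ₚ = 0.95 and
0.92); both score IGR = 1 (each alone splits the groups perfectly); the
wrapper keeps both at CV accuracy 1.0; and the pair separates the groups
with hard margin 2.10 in z-scored units. Effect-size arithmetic is also
available directly — `partial_eta_squared_from_f(13.084, 1, 23)` returns
`0.3626`, i.e. a reported F(1, 23) = 13.084 corresponds to η²ₚ = 0.363.

For a one-shot run there is `run_pipeline(pipeline_config(...))` (writes
a report bundle: `results.json`, screen/ranking/trace CSVs, a manifest
with seed and config fingerprint) and a thin command-line wrapper in
`inst/cli/morphoclass.R` with `simulate` and `run` subcommands.

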