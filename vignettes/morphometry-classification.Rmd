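---
title: "Morphometric screening and wrapper classification: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Morphometric screening and wrapper classification: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Orthostatic tremor (OT) and essential tremor (ET) are clinically adjacent
diagnoses that are regularly confused, and case–case discrimination from
structural MRI is an attractive complement to the clinical exam. The data
situation is typical of rare-disease neuroimaging: a few dozen subjects
(here 14 vs 15), a few hundred regional morphometry features per subject
(281 with the default catalog), and clinical covariates — age, sex, years
of education, tremor duration — that must be adjusted for before any group
difference is believed.

`morphoclass` implements that analysis as a reusable, testable pipeline:

1. **Feature construction** — regional statistics tables (aseg/aparc
   dialect) are assembled into a subjects × features matrix: per cortical
   region and hemisphere a grey volume, a mean cortical thickness, and a
   *roughness*; per subcortical structure a volume normalized both by
   total intracranial volume (ICV) and by total grey-matter volume (GM);
   plus raw ICV.
2. **Covariate-adjusted screening** — per-feature ANCOVA with the group
   term's partial F and partial eta-squared.
3. **Information-gain-ratio (IGR) ranking** of the screened features.
4. **Greedy forward-wrapper selection** driven by 10-fold cross-validated
   accuracy of a linear SVM.
5. **Evaluation** — hard-margin linear-separability reporting, an
   exhaustive subset-search oracle, scatter-matrix figures, and a subgroup
   re-run of the same machinery.

Every stage is exercised against a synthetic cohort generator, so the
statistical behaviour of the pipeline (calibration, power, null honesty)
is tested in CI rather than asserted.

## Roughness

For a cortical region, roughness is the standard deviation of cortical
thickness within the region, in mm. Mean thickness can be preserved while
thinning proceeds non-uniformly; roughness captures exactly that
non-uniformity, which is why it enters the feature set alongside the mean.
`compute_roughness()` uses the sample (n−1) standard deviation; when a
stats table already carries a thickness-SD column it is taken as-is. The
denominator convention is ours to fix — at the vertex counts of real
parcellations (thousands per region) the difference is far below
measurement noise.

## ANCOVA screening

For feature $y$ the model is

$$y = \beta_0 + \beta_g\,g + \beta_1\,\mathrm{age} + \beta_2\,\mathrm{sex}
      + \beta_3\,\mathrm{educ} + \beta_4\,\mathrm{dur} + \varepsilon,$$

with $g$ a 0/1 group indicator. The group test is the partial F from the
nested residual-sum-of-squares comparison (full vs group-dropped), which
for a single two-level factor is identical to the Type-II and Type-III
tests, so the unstated sums-of-squares convention of the source toolchain
is moot. With $n = 29$ and four covariates, $df_1 = 1$ and
$df_2 = 29 - 6 = 23$. The effect size is partial eta-squared,

$$\eta_p^2 = \frac{F \cdot df_1}{F \cdot df_1 + df_2},$$

exposed directly as `partial_eta_squared_from_f()` so reported F
statistics can be converted and checked without refitting. Tremor duration
is included among the covariates because it is the one demographic that
genuinely differs between the groups; adjusting for it is what makes the
morphometric contrasts case–case rather than duration-of-illness effects.

Screening keeps features with $p < \alpha$ (default 0.05) **without**
multiple-testing correction. That mirrors the analysis this package
models, and it is defensible there because the screen is a pre-filter for
a wrapper whose own currency is cross-validated accuracy — but it means
the screened list itself must never be read as a family of confirmed
group differences; reports label it uncorrected.

Degenerate inputs are handled explicitly: a constant feature returns
$F = 0$ with a warning; constant covariates are dropped (reducing the
model to fewer parameters, e.g. the two-sample t-test when all four are
constant); genuinely collinear covariates are an error naming the columns.

## Information gain ratio on continuous features

The discretization used by the original toolchain is unstated, so the
package fixes the simplest deterministic choice with an exact brute-force
oracle: the single best binary midpoint split. Candidate thresholds are
midpoints between consecutive distinct sorted values; for a threshold
splitting $n$ subjects into sides of size $n_1, n_2$,

$$IG = H(Y) - \tfrac{n_1}{n} H(Y_1) - \tfrac{n_2}{n} H(Y_2), \qquad
  SI = -\tfrac{n_1}{n}\log_2\tfrac{n_1}{n} - \tfrac{n_2}{n}\log_2\tfrac{n_2}{n},$$

and $IGR = IG / SI$, maximized over thresholds (entropies in bits). The
ratio normalizes gain against the split's own entropy, the standard
remedy for gain's bias toward unbalanced splits. IGR lies in $[0, 1]$, is
1 exactly when some threshold separates the classes perfectly, and is
invariant under strictly increasing transformations of the feature. Ties
between thresholds break to the lower value; ties between features break
lexicographically — both purely for determinism.

## The greedy forward wrapper

The subset starts as the top-ranked feature with its cross-validated
accuracy. Each subsequent feature, in rank order, is tentatively added
and kept **iff** CV accuracy is equal or higher than the current best;
the walk ends when every ranked feature has been tried once. Two details
matter in a 29-subject cohort:

* The fold plan is **frozen** across all steps (stratified by class,
  seeded), so subset accuracies are comparable numbers rather than
  re-randomized estimates. Whether the original analysis re-drew folds
  per subset is unknown; freezing is the choice that makes the procedure
  a pure function of (data, seed).
* Accuracy comparisons use exact pooled **correct counts**, not floating
  ratios, so the "equal or higher" rule cannot be corrupted by float
  rounding. The keep-on-equal rule means the final subset can contain
  uninformative passengers; the separability report, not subset
  membership, is the interpretable output.

### Classifier settings

The reference configuration is a linear-kernel ("dot kernel") SVM with
convergence tolerance $10^{-3}$ — both mapped directly onto the
underlying libsvm implementation. Its quoted "complexity constant = 0.0"
has no meaning for a soft-margin SVM ($C = 0$ admits the trivial
solution), so the package uses the conventional default $C = 1$ and
records it in every trace and manifest. The kernel cache size is a
performance knob with no numerical effect and is ignored. Features are
z-scored within each training fold before fitting — raw morphometry mixes
mm³-scale volumes with mm-scale thicknesses, and an unscaled dot product
would let volumes dominate. Training folds that lose a class (possible
only in tiny subgroups) predict the one class present, with the event
logged.

### Cross-validation plans

Folds are stratified: each class is shuffled with the seeded generator
and dealt round-robin, so fold sizes differ by at most one and per-fold
class counts are within one of proportionality. For subgroup contrasts
where the smaller class is below the fold count (e.g. 9 vs 5), a
stratified 10-fold plan is ill-posed; the plan downgrades to
leave-one-out with a warning. This is our resolution of an ambiguity in
the source procedure, chosen because leave-one-out is the deterministic
limit of the same estimator.

## Separability and the exhaustive oracle

"Linear separation in Euclidean distance terms" is operationalized as the
hard-margin width of the maximum-margin hyperplane: on (by default
z-scored) features, `linear_separation()` solves the maximum-margin
problem via a linear SVM at cost $10^6$ and declares the subset separable
when no training point violates the unit margin beyond a $10^{-3}$ slack;
the reported margin is $2 / \lVert w \rVert$. Margins below roughly
$2/\sqrt{10^6}$ would be reported as non-separable — far below any
configuration of interest here. The tests cross-check the margin against
an independent KKT active-set enumeration.

`exhaustive_subset_search()` evaluates every subset up to `max_size` on
the same frozen plan and is the oracle the greedy path is tested against
(greedy can never beat it). Enumeration is guarded (> 20 features with
`max_size` > 4 is refused) because its cost is the reason the greedy
wrapper exists at all.

## The synthetic cohort generator

`synthetic_spec()` defaults encode the study conditions the package
models: groups of 14 and 15; age $\mathcal{N}(65.0, 13.9^2)$ vs
$\mathcal{N}(68.5, 8.3^2)$ years, education $8.0 \pm 4.9$ vs
$6.9 \pm 3.1$ years, tremor duration $9.4 \pm 6.9$ vs $24.9 \pm 18.4$
years (all truncated at zero), sex (female) with probabilities 12/14 vs
11/15; and the 281-feature catalog (34 cortical regions × 2 hemispheres ×
{volume, thickness, roughness} + 38 subcortical structures × {/ICV, /GM}
+ ICV). Only summary statistics are available for the source cohort, so
normal distributions are the minimal assumption; the zero-truncation of
tremor duration in the wider group shifts its realized mean upward by
about 3 years, which is accepted rather than corrected because the
generator's purpose is structural, not distributional, fidelity.

Features are drawn as
$\mathrm{baseline} + \sigma s (d\,g + z) + \mathrm{leakage}$, with $z$
standard normal, $s$ the feature's catalog scale, $\sigma$ the global
`noise_sd`, and $d$ the planted standardized effect (signed group B −
group A, matching the direction convention of the adjusted-difference
column in reports). /GM-normalized subcortical columns are **derived**
from the /ICV draw through the subject's ICV/GM ratio rather than drawn
independently — that keeps both normalizations of one structure coherent
with a single underlying raw volume, which is what makes the
FreeSurfer-dialect writer → reader → assembler round trip exact. The
price is that effects must be planted on the /ICV variant (a validation
error says so), and that /GM columns inherit mild ICV/GM-ratio noise.

`make_separable_cohort()` rewrites $k$ designated feature columns so each
informative coordinate carries a group gap of $m s/\sqrt{k}$ with
folded-normal noise pushed outward; along the diagonal direction the two
groups are then at least $m$ apart in per-feature scale units, for any
noise level, with all other features null. Individual informative
features are themselves separating — a deliberately benign geometry whose
purpose is a *guaranteed* ground truth for pipeline recovery tests, not a
hard benchmark.

What the generator does **not** emulate: spatial correlation among
regions (real neighboring regions co-vary strongly), heavier-than-normal
tails, scanner/site effects, and any true covariate–disease confounding
unless injected via `covariate_leakage`. Passing tests therefore
demonstrate that the machinery is correct and calibrated under clean
conditions; they do not certify performance on real cohorts.

## Problem sizes in the simulation studies

The shipped tests and the acceptance script size their simulations as
follows (the package's own choices, balancing Monte-Carlo error against
run time): calibration and power studies use 100–200 replicate cohorts;
pipeline-recovery runs use 25–50 separable cohorts of 54 features;
permutation nulls use 200 label shuffles; greedy-vs-exhaustive
comparisons use 10–12-subject, 8–10-feature instances where full
enumeration (up to $2^{10}-1$ subsets) is affordable. The permutation
band is the binomial 95% interval for a single 29-subject cohort around
the majority-class rate 15/29; the permuted statistic is the CV accuracy
of a fixed feature subset, because re-running the selection under
permuted labels measures wrapper selection bias rather than the null
behaviour of the accuracy estimator.

## Known limitations

* With 29 subjects, 10-fold CV accuracy has a granularity of 1/29 ≈ 3.4
  points; "100% accuracy" on such cohorts is a statement about one small
  sample, not a generalization claim. The permutation-null tooling is
  included precisely so users can see what chance looks like.
* The uncorrected screen passes ~5% of null features by construction;
  downstream stages must (and here do) tolerate noise features.
* The keep-on-equal wrapper rule inflates subset size on flat accuracy
  plateaus.
* Cortical volumes are left unnormalized (matching the reporting
  convention the package follows, where subcortical volumes carry /ICV
  and /GM variants but cortical contrasts are in raw mm³); users wanting
  normalized cortical volumes can construct the catalog accordingly.
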