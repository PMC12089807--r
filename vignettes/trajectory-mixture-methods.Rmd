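---
title: "Methods: mixture-based symptom trajectories, one-vs-rest forests, and permutation inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mixture-based symptom trajectories, one-vs-rest forests, and permutation inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

This vignette documents the statistical methods, numerical choices and
design decisions behind `trajmix`. The package analyses two repeated
measurements of a bounded integer symptom-severity score (0–63, e.g. the
Beck Depression Inventory) per participant, plus a table of baseline
clinical and psychosocial features.

## 1. Univariate Gaussian mixtures

`fit_gmm1d()` fits, by expectation–maximisation, the k-component model

$$ p(x) = \sum_{j=1}^{k} \pi_j \, \mathcal{N}(x \mid \mu_j, \sigma_j^2), $$

with component-specific variances. Numerical choices:

- **Weighted EM on distinct values.** Severity scores are integers, so a
  cohort of hundreds collapses to at most 64 distinct values. The E- and
  M-steps run on the distinct values with multiplicity weights (in C++),
  which is algebraically identical to running on the raw vector and an
  order of magnitude faster. Responsibilities are expanded back to the raw
  observations on return.
- **Log-space E-step.** Component log-densities are combined through a
  log-sum-exp, so small likelihoods do not underflow.
- **Variance floor.** Each $\sigma_j^2$ is floored at $10^{-4}$ times the
  overall sample variance. Without a floor the likelihood of a
  heteroscedastic univariate mixture is unbounded (a component can collapse
  onto one point); the floor keeps EM ascent within a compact region.
- **Restarts.** 10 restarts per fit; the first is seeded at the empirical
  quantiles of the data (evenly spaced), the rest at random draws from the
  data. The best final log-likelihood wins.
- **Convergence.** Absolute log-likelihood change below $10^{-6}$, at most
  500 iterations. The full log-likelihood trace is returned, and the test
  suite asserts it is non-decreasing for every fit.
- **Degeneracy guards.** Inputs must be finite with at least $2k$ distinct
  values; inputs that cannot support $k$ components are an error, not a
  silent collapse.

The returned `gmm1d` object follows the classic R modelling idiom:
`print`, `summary`, `coef`, `logLik` (df $= 3k - 1$), `AIC`/`BIC` via
`information_criteria()`, `predict` (class, responsibilities, density),
`simulate`, `plot`.

## 2. Choosing the number of components

`select_k()` fits each candidate $k$ (default 2–12) and scores the hard
assignment by the mean silhouette with the 1-D absolute-difference metric.
On sorted values the per-point mean distances to each cluster can be
computed from prefix sums in $O(n \log n)$; the test suite checks this
implementation against an $O(n^2)$ brute-force oracle at $10^{-12}$.
Conventions: singleton clusters contribute a silhouette of 0; ties in the
best silhouette resolve to the smallest $k$ (parsimony); a fit whose hard
assignment uses fewer clusters than $k$ is recorded as failed for that $k$.
AIC and BIC are reported per $k$ in the diagnostics table so the
fit-versus-complexity trade-off can be inspected, but selection is by
silhouette alone.

## 3. Trajectory labels

`order_by_severity()` ranks components by mean (ties by variance);
`binarize_severity()` maps the lowest-severity cluster to `low` and merges
all remaining clusters into `high` — with three clusters at a timepoint,
the moderate and severe clusters are combined, since both represent symptom
levels needing clinical attention. Crossing the two binarised timepoints
yields the four classes:

| baseline | follow-up | class |
|---|---|---|
| low | low | good_prognosis |
| high | low | remitting_course |
| low | high | clinical_worsening |
| high | high | persistent_course |

`summarize_trajectories()` reports counts, percentages, and the derived
baseline-low and follow-up-low percentages (rounded to 2 decimal places).

## 4. One-vs-rest random forests

One probability forest per class (positive class vs the other three),
fitted with `ranger` at 500 trees. The tuned hyperparameters are the
splitting criterion, class weighting (`none` or `balanced`, the latter
weighting classes by $n / (2 n_c)$), maximum depth (0 = unlimited), the
fraction of features considered per split, and the minimum samples per leaf
and per split.

**Design decision — splitting criterion.** `ranger` does not implement an
entropy (information-gain) criterion for classification. The search space
therefore offers `gini` and `extratrees` (random-split) as the two
criterion levels: both are impurity-decrease criteria available natively,
preserving a two-level categorical criterion dimension rather than
silently collapsing it.

**Tuning.** `tpe_optimize()` is a self-contained tree-structured Parzen
estimator: after `n_startup` random trials, trials are split at the
$\gamma = 0.25$ quantile of the objective into good/bad sets; numeric
parameters get Parzen (kernel) densities with bandwidth one tenth of the
range plus a uniform prior component, integers are rounded, categoricals
use add-one re-weighted counts. Each step scores 24 candidates by
$\log \ell(x) - \log g(x)$ and evaluates the best. The objective is the
mean inner-cross-validation F1.

**Nested cross-validation.** Outer 10-fold, repeated 5 times, with inner
5-fold tuning inside every outer training set (so outer test rows never
influence tuning). Folds are stratified on the binary target. Outer folds
without positive test cases are skipped with a warning and reported.
Metrics per fold: F1 (defined as 0 when precision + recall = 0), accuracy,
AUROC (rank/Mann–Whitney with midrank ties), AUPRC (average precision), and
a pooled row-normalised confusion matrix.

## 5. SHAP attributions

`shap_attributions()` implements exact path-dependent TreeSHAP in C++
(polynomial-time extension/unwinding over decision paths), applied to the
positive-class probability output of each tree and averaged over trees.

**Cover convention.** `ranger` does not expose per-node training counts,
so node covers are reconstructed by routing the model's stored training
data through each tree (`x <= split` goes left, matching `ranger`'s split
semantics, verified empirically). The base value is the cover-weighted mean
leaf value, i.e. the mean model output over the training data. Under this
convention the attributions are *exactly* the Shapley values of the
path-conditional expectation game: the test suite checks equality with a
brute-force enumeration over all feature coalitions at $10^{-9}$, and local
additivity (base + attributions = prediction) at $10^{-6}$ on full
forests.

`direction_summary()` turns attributions into sign calls per feature via
the Spearman rank correlation between feature values and attributions
(|ρ| ≥ 0.1 for a call; zero-variance columns are flagged and reported
`mixed`).

## 6. Permutation inference

The null model is "no association between features and trajectory class".
One draw (`permuted_run()`) shuffles the whole four-class label vector once
— outside the cross-validation loop, the same permuted vector feeding all
four one-vs-rest targets, which preserves the class imbalance and the
correlation structure among targets — and recomputes (a) the outer-CV mean
F1 per class and (b) the full-data refit impurity-importance vector per
class. Hyperparameters stay frozen at their tuned values; an MD5 checksum
of the frozen set is asserted constant across draws, so re-tuning inside
the null is structurally impossible.

With $B$ draws, one-sided p-values use the add-one estimator
$p = (1 + \#\{T^{null} \ge T\}) / (B + 1)$ (ties count against the
alternative; $p$ is never 0). Benjamini–Hochberg adjustment (via
`stats::p.adjust`) is applied *within* each family — the 4 performance
tests and the $4 \times p$ importance tests — because the two families
answer different questions at different scales.

## 7. Synthetic cohort generator

`generate_cohort()` plants a known truth to validate every stage:

- Class memberships are multinomial with configurable proportions
  (default 155/174/85/369 out of 783).
- Baseline severity is a two-component mixture (defaults: 31% at mean 9,
  sd 4; 69% at mean 24, sd 7) with the component tied to the class's
  baseline level; follow-up severity is normal with class-specific mean/sd
  (good 6/3, remitting 8/3, worsening 26/5, persistent 32/7). Scores are
  rounded to integers and clipped to [0, 63] — the instrument is
  integer-valued and bounded, and under the default geometry clipping
  touches well under 1% of draws.
- 32 features (8 continuous, 20 binary, 4 ordinal). Four carry planted
  class effects with a plausible directional structure (worse quality of
  life, higher stress and disability, NYHA class III pushing towards the
  persistent course); the rest are exchangeable noise. Continuous effects
  shift means in sd units; binary effects shift log-odds; ordinal features
  cut a shifted latent normal.
- `null_cohort()` zeroes all effects, giving exact feature–class
  exchangeability for calibration tests.
- `export_ground_truth()` writes the planted labels and effect matrix so a
  pipeline run can be scored against truth.

All randomness is seeded; `generate_cohort()` with the same configuration
is bit-reproducible, and every pipeline stage derives its seed from the
master seed.

## 8. Execution profiles and reproducibility

`run_config()` bundles the budgets: the `full` profile (10×5 outer folds,
500 TPE evaluations, 500 trees, B = 1000) mirrors study-scale settings and
is hours-scale on one CPU; the `ci` profile (3×1 outer folds, 12
evaluations, 150 trees, B = 100, SHAP on 250 sampled rows) exercises the
identical code paths in minutes and is used by the test suite and the
acceptance script. Problem sizes in the test suite (cohort sizes, tree
counts, permutation budgets) were likewise chosen for the test-time budget
and stated power, as the package's own testing choices.

Every `run_pipeline()` result carries a manifest: the configuration echo,
seeds, trajectory counts and headline F1 values, plus an MD5 content hash —
reruns with the same configuration and seed produce the identical hash.

## 9. Limitations

- Clustering is univariate per timepoint; joint longitudinal mixture
  models (random-effects trajectories over more than two timepoints) are
  out of scope.
- Impurity importance is biased towards high-cardinality features; it is
  reported alongside SHAP, and inference on it is by permutation, which
  removes the bias from the *test* but not from the ranking.
- Path-dependent TreeSHAP conditions on the tree structure rather than a
  background distribution; attributions can differ from interventional
  SHAP when features are strongly correlated.
- The permutation null shuffles whole label vectors, testing global
  association; it does not test conditional independence of individual
  features.
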