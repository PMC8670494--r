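---
title: "Transformational learning across related regression tasks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transformational learning across related regression tasks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

Scientific data often arrive as many small, related regression tasks: QSAR
assays that each relate a molecular fingerprint to activity against one
protein target, per-gene expression models under shared experimental
conditions, per-dataset performance models of learning algorithms. Each task
$T_i$, $i = 1..n$, shares one intrinsic representation: a common set of $p$
attributes $X = (x_1, \dots, x_p)$, with a task-specific numeric response
$y_i$.

The standard approach fits each task separately on the intrinsic attributes
with a baseline method $A$, giving models $A_i = A(X_i) \approx y_i$. The
transformational approach instead represents every example *extrinsically*,
by what the already-trained models of the other tasks predict about it, and
fits a meta-model $\Phi$ on that representation:

$$\Phi(X_{new}) = \Phi(A_1(X_{new}), A_2(X_{new}), \dots, A_n(X_{new}))
  \approx y_{new}.$$

The procedure has exactly two stages: (1) apply the $n$ source models to the
examples of the task at hand, collecting their predictions as the new
feature columns; (2) fit any learner on those columns. The justification is
that the source models encode regularities of the shared domain — an example
is described by its "profile" against everything the collection already
knows — so the transformed space is low-dimensional, response-scaled, and
already nonlinearly processed.

Two conventions matter and are both implemented:

* **Leave-own-model-out.** For a task inside the collection, its own source
  model is excluded from its representation (`exclude_task` in
  `tml_transform()`, on by default in the evaluation protocol); otherwise a
  model trained on the very examples being re-represented would leak its
  memorized targets into the features. For a genuinely new task all $n$
  models contribute. `include_self = TRUE` overrides.
* **Source models are trained once on their own full tasks.** When the
  evaluation cross-validates task $i$, the other tasks' source models are
  not retrained per fold. If example sets overlap across tasks this leaves
  a residual leakage channel (an evaluation example of task $i$ may be a
  training example of task $j$); the per-task targets differ, so the leak
  is indirect, but it is real and is documented rather than hidden. The
  transform itself never leaks: the excluded-model check and the
  column-drop identity are asserted exactly in the test suite.

## Learners

Five baseline families are wrapped behind one deterministic contract
(`fit_learner()` / `predict()`): random forest (ranger), gradient boosting
(xgboost), RBF support-vector regression (e1071), k-nearest neighbours
(caret), and a single-hidden-layer neural network (nnet). Scale-sensitive
families (knn, nn; svm via its own scaling) standardize their inputs
internally and uniformly, so intrinsic and transformed representations pass
through one code path. Defaults (500 trees with $\sqrt p$ candidate splits;
200 boosting rounds at depth 3, learning rate 0.1; RBF cost 1 with
$\gamma = 1/p$; $k = 5$; 64 hidden units, weight decay 0.01) are
conventional, shipped both in code and as YAML, and overridable;
`tune_learner()` grid-searches them by seeded cross-validated RMSE with
ties broken by grid order and failed grid points scored $+\infty$. All fits
are single-threaded with fixed seeds; the neural network is documented as
deterministic-per-platform only.

A zero-variance target is not an error: the fit degenerates to the constant
predictor and is flagged, so constant source models pass through the
transform as constant columns rather than being silently dropped.

## Stacking

The two prediction streams (baseline and transformational) are combined by
the simplest form of stacking — combining predicted outputs:

* **Convex**: nonnegative least squares, $\min \|y - Pw\|^2$, $w \ge 0$,
  no intercept and no sum-to-one constraint (predictions already share the
  target's scale). Solved by the Lawson–Hanson active-set algorithm; the
  feasible set contains every unit vector, so the training RMSE of the
  stack can never exceed that of any single stream — asserted exactly in
  the tests. Rank-deficient panels have multiple optima; the deterministic
  active-set solution is returned and flagged. An optional simplex mode
  renormalizes the weights for sensitivity analysis.
* **Ridge**: closed-form normal equations on the column-centered panel,
  intercept recovered from the means, penalty chosen from
  $\{0.01, 0.1, 1, 10, 100\}$ by 5-fold cross-validated RMSE with ties to
  the smallest $\lambda$; $\lambda = 0$ is dropped automatically when the
  Gram matrix is numerically singular (condition number above $10^{10}$).

Stacking weights are always fit on out-of-fold predictions, never on
resubstitution predictions. Inside the benchmark this is implemented as a
second-level cross-validation over the out-of-fold panel with the same fold
partition: the weights scoring fold $f$ are fit on the other folds' rows.

## Evaluation protocol

`run_benchmark()` scores every requested variant (baseline, transformed,
combined, stacked convex/ridge) on every task by k-fold cross-validated
RMSE (default 10 folds), with one fold partition per task shared across
variants so the paired comparisons are split-for-split. The partition is
seeded by the configuration seed and the task size; identical tasks
therefore receive identical splits and identical RMSEs. Summaries report
the mean RMSE over tasks (and the median alongside, since the sign test
addresses medians), and percentage improvement as
$100(1 - \overline{RMSE}_{variant}/\overline{RMSE}_{baseline})$.

Two paired tests compare each variant against the baseline over the
per-task RMSE pairs:

* **Sign test** — exact two-sided binomial on the sign counts (doubled
  tail, capped at 1). Zero differences are discarded and their count
  reported, the classical convention.
* **Wilcoxon signed-rank** — zeros discarded, average ranks for ties. The
  null distribution is exact for $n \le 25$, computed by
  generating-function convolution over doubled ranks (equivalent to full
  $2^n$ sign-assignment enumeration, and valid under ties, which the
  standard exact implementation does not handle); beyond that a
  tie-corrected normal approximation with continuity correction is used.
  The tests verify both regimes against brute-force enumeration.

Tasks too small to leave at least two training rows per fold are skipped
with a recorded reason and the summary is computed over the evaluated
tasks; a learner family failing on more than 20% of tasks aborts the
benchmark with a task-level report.

## Interpretation

`attribute_importance()` ranks the source-task columns of a
transformational model: native impurity/gain scores where the family has
them, mean RMSE increase over seeded column permutations otherwise (the
automatic fallback is recorded). Weights are reported as percent-of-total
by default — the natural reading of published importance tables — with a
raw mode available, since the scale is a presentation choice, not part of
the method.

`example_profiles()` (examples × task models) and `problem_profiles()`
(task models × probe examples; exactly the transpose on the same inputs)
feed `hierarchical_cluster()`. The default distance is correlation
($1 - r$) with average linkage: prediction profiles carry functional
similarity in their shape, not their scale. This default is a documented
assumption, configurable to Euclidean/complete/Ward. Correlation distance
is undefined for constant profiles; those are an error naming the rows.
Trees export to Newick via `ape`, and `cut_clusters()` labels clusters
deterministically by smallest contained leaf index.

## The synthetic benchmark generator

Since the corpora behind published multi-task benchmarks run to ~100 GB,
the package ships a generator (`generate_tasks()`) that emulates the
*statistical* structure the method assumes, with no chemical realism:

* features: 1,024-bit-fingerprint-like sparse binary columns (per-bit
  frequency Beta(0.3, 1)) or Gaussian;
* a shared latent structure $z = xB$ ($B$: $p \times k$ loadings) — the
  "regularity of the world" all tasks see;
* task coefficient vectors $w_i = \sqrt\rho\, \bar w + \sqrt{1-\rho}\, u_i$,
  so the relatedness dial $\rho$ is exactly the expected coefficient
  correlation (verified by simulation in the tests); an optional group
  structure plants within/between-group relatedness blocks;
* targets $y_i = f(z^\top w_i) + \varepsilon$, $\varepsilon \sim N(0,
  \sigma^2)$ with $\sigma = 0.5\,\mathrm{sd}(signal)$ by default, and
  $f$ = tanh of the standardized index by default — with a purely linear
  truth, kernel and forest baselines already saturate and the
  transformation has little room to help;
* a shared example pool (`overlap_fraction`, default 0.3) mirrors the
  second relatedness channel of real assay panels: the same molecules
  appear in many assays.

The default benchmark ("experiment A": 60 tasks × 100 examples, $p = 128$,
$k = 10$, $\rho = 0.9$) keeps tasks deliberately small — the method's
premise is many related *small* tasks — while staying comfortably inside a
laptop-scale compute budget; these are also the problem sizes the test
suite and the acceptance script use. What passing tests on this generator
do show: the transformed representation beats the intrinsic one when task
functions are related, and yields no systematic gain when they are not
($\rho = 0$), with honest out-of-fold evaluation. What they do not show:
anything about real fingerprints (no substructure correlations), real
assay noise, task-size heterogeneity, or distribution shift between tasks.

## Numerical and design choices

* Fold assignments, permutations and all stochastic fits derive from
  explicit integer seeds; derived seeds stay below $2^{31}$.
* Learner digests are canonical strings of family + sorted
  hyperparameters + seed, so registries are insertion-order independent
  and transformed columns are always sorted by source task id.
* Transformed columns are used raw (no standardization): they share the
  target's scale by construction; scale-sensitive learners standardize
  internally anyway.
* With $\rho = 0$ the generator's tasks still share the latent loadings
  $B$, so their *feature geometry* is related even though their response
  functions are not; a small, usually non-significant transformed-feature
  gain can appear through that channel. The unrelated-task control
  therefore asserts non-significance of the paired sign test across
  replicate collections rather than a point null.
* Feature selection over transformed columns (`select_tml_features()`)
  scores by absolute Pearson correlation (forest importance as the
  fallback for constant targets) with ties broken by column order —
  data-driven selection only; semantics-driven selection (e.g. target
  homology) is out of scope.
* The registry persists models as an index plus serialized blobs and
  refuses to load other format versions outright: an explicit
  incompatibility error is preferable to silent misprediction.

## Known limitations

* Second-order transforms re-derive first-order features on the fly, so
  their cost grows with $n^2$ model applications; fine at benchmark scale,
  noticeable beyond.
* The neural-network family is the slowest and least deterministic across
  platforms; it is excluded from the default benchmark configuration.
* No classification targets, no missing-value handling (representations
  are assumed complete), no SMILES/fingerprint computation from structures.
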