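---
title: "Synthetic random forests: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Synthetic random forests: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synforest)
```

## The idea

A random forest is a locally weighted averaging estimator: its prediction at
a point is a convex combination of training outcomes, with weights determined
by how often cases co-occupy terminal nodes. Of the forest's three tuning
parameters (`ntree`, `mtry`, `nodesize`), the terminal node size acts as the
bandwidth of this smoother — large nodes smooth heavily, size-1 nodes barely
at all — and the best bandwidth depends on the data, and can even vary across
the feature space when the target function's curvature does.

The synthetic random forest (SRF) sidesteps global bandwidth selection by
making it local. It grows a portfolio of $D$ forests
$\mathrm{RF}_1, \dots, \mathrm{RF}_D$ over a grid of nodesize values
$n_1 < \dots < n_D$ (everything else held fixed), takes each machine's
*out-of-bag* prediction at every training case as a new input column — a
*synthetic feature* — and fits a secondary forest, the *hyperforest*, on the
original $p$ features plus the $q$ synthetic ones. Node splits of the
hyperforest can then choose, locally, which bandwidth's predictions to trust.

Three baselines complete the picture:

* **RF** — a single forest at `nodesize = 5`, the same value the hyperforest
  uses, so the two differ only by the synthetic columns;
* **RFopt** — the single portfolio machine whose nodesize minimizes
  out-of-bag error: a *globally* tuned forest;
* **COBRA** — the combined-regression-alternative collective over the same
  machines. COBRA predicts by averaging the outcomes of training cases whose
  machine predictions all (or a set fraction) lie within $\varepsilon$ of the
  machine predictions at the test point. Its local weights are exactly 0 or
  1; contrasting it with the hyperforest isolates the value of the forest's
  richer convex weights.

## Out-of-bag discipline

Each tree's bootstrap leaves out about $36.8\%$ of the cases
($(1 - 1/n)^n \to e^{-1}$); aggregating, for case $i$, only trees whose
bootstrap excluded $i$ yields a prediction that never saw $y_i$. Synthetic
features are always built this way — using full-forest predictions at
training time would let the hyperforest read the response off a single
column and overfit catastrophically. The package asserts this discipline two
ways: structurally (the out-of-bag aggregate for case $i$ provably uses no
tree with `inbag[t, i] > 0`) and statistically (on a permuted-response
dataset the full SRF pipeline scores at the uninformed anchor — standardized
MSE near 100, Brier near 25 — while in-bag predictions would score far
better).

At `ntree = 500` every case is out-of-bag for some tree with overwhelming
probability ($1 - 0.632^{500}$ per case). For tiny ensembles an uncovered
case is flagged `NA`; when a complete column is required the package imputes
the full-forest prediction for just those cases, a documented compromise that
keeps the pipeline total without weakening the covered cases.

For *new* cases (prediction time) no discipline is needed — they are
out-of-sample for every machine — so the test-time synthetic columns are
full-forest predictions from the stored components.

## Parameters and defaults

| parameter | default | meaning |
|---|---|---|
| `nodesize_grid` | 1–10, 20, 30, 50, 100 | bandwidth grid; pruned to values `< n` |
| `ntree` | 500 | trees per forest; performance is flat above a few hundred |
| `mtry` | first integer $> p/3$ | split candidates; recomputed as $> (p+q)/3$ for the hyperforest |
| `hyper_nodesize` | 5 | hyperforest bandwidth; results are insensitive to it |
| `eps` (COBRA) | calibrated | 200-point linear grid over the machines' prediction spread |
| `alpha_frac` (COBRA) | 1 | fraction of machines that must agree (1 = unanimity) |

Notes on the open choices:

* The grid endpoints follow the guidance of small + intermediate + large
  values. The exact grid used in the reference experiments is not recorded,
  so the grid is a first-class configuration field and the benchmark
  tolerances are Monte-Carlo-wide.
* The mtry rule is read *strictly* ("first integer greater than $p/3$",
  i.e. $\lfloor p/3\rfloor + 1$), which differs from `ceiling` only at
  multiples of 3; a switch selects the other reading. For the hyperforest
  the rule is applied to the augmented dimension $p + q$ (the rule is fixed,
  the dimension is not); a switch applies it to $p$ instead.
* Node sizes count bootstrap copies rather than *unique* cases; with
  continuous features and desk-scale n the distinction is immaterial.
* Split criteria are variance reduction (regression) and Gini (multiclass);
  ties among equal-gain splits fall to the first candidate encountered under
  the seeded feature draw. Randomized splitting (`nsplit`) is deliberately
  not implemented.
* COBRA's agreement rule defaults to unanimity (`alpha_frac = 1`), matching
  the original method; `0.5` reproduces the "majority of machines" reading.
  An empty neighbour set falls back to `mean(train_y)` with a warning rather
  than erroring, keeping cross-validation folds total. Calibration on the
  training set excludes each case from its own neighbour set. Multiclass
  COBRA is unsupported.
* For multiclass machines the last of the $J$ probability columns is dropped
  (they sum to 1), giving $q = D(J-1)$; RFopt's out-of-bag error is the
  normalized Brier score (switchable to misclassification rate).

## Seeding

All randomness flows from integer seeds. Component forest $j$ seeds with
`base_seed + j`, the hyperforest with `base_seed - 1`, the plain-RF baseline
with `base_seed - 2`; the replication harness draws per-replication seeds
from its base seed, and every method inside a replication sees the identical
train and test draws. Two runs from the same configuration are byte-identical.

## The generators, and what a green test establishes

The simulated benchmarks are the canonical Friedman regression surfaces and
Gaussian classification mixtures, written out in full in the reference pages
(`?gen_friedman1`, `?gen_gaussian_classif`): smooth, high-signal, sparse
surfaces with known inert features, independent train/test draws, balanced
classes, and Gaussian or uniform feature distributions. They emulate the
regime where bandwidth adaptivity pays off — high signal, sparse solutions —
and deliberately *not* the messiness of real data: no missing values, no
mixed types, no covariate shift, no class imbalance, no feature correlation
beyond what the mixtures imply. A green benchmark test therefore establishes
that the implementation reproduces the published simulated-suite behaviour
(SRF $\le$ RFopt $\le$ RF, means near the published table rows); it says
nothing about real-data performance, where the published gaps are smaller.

One convention is genuinely ambiguous across sources: the ringnorm mean
constant for the tight class ($1/\sqrt d$ versus $2/\sqrt d$). The package
follows the benchmark-collection convention ($1/\sqrt d$) and exposes
`ringnorm_a`.

The `.noise` rows of the published tables (inflated noise variants) use
multipliers that are not recorded; the noise level is a generator parameter
here, but those rows are excluded from the acceptance checks.

## Metrics and rank statistics

Standardized MSE is $100 \cdot \mathrm{MSE} / \mathrm{Var}(y)$ with the
population variance of the evaluation vector (for cross-validation, of the
full response), so predicting the mean scores exactly 100. The multiclass
Brier score is normalized by $J/(4(J-1))$ — the unique linear scaling under
which uniform guessing scores 25 for every $J$ — and multiplied by 100.

Method comparisons across datasets use the exact Wilcoxon signed-rank test
(zeros dropped, midranks for ties, exact null distribution by convolution up
to $n = 25$, tie-corrected normal approximation beyond; two-sided by
default) and the Iman–Davenport modified Friedman test
$F = (b-1)\chi^2_F / (b(k-1) - \chi^2_F)$ on the average ranks. The
published overall-rank tables pool dozens of real datasets that are out of
scope here; the statistics are exercised on simulated suites and hand-built
fixtures instead.

## Numerical and degenerate-input choices

* `nodesize` is a splittability threshold, as in the reference forest
  implementation: a node is split while it holds at least `2 * nodesize`
  bootstrap cases and the best candidate split strictly improves the
  impurity (beyond a $10^{-10}$ relative guard), and daughters may end up
  with as little as one case. (The stricter reading — every terminal node
  keeps `nodesize` cases — was implemented first and measurably hurt
  benchmark accuracy; the reference semantics are kept.) Pure nodes and
  constant features stop cleanly.
* `nodesize = n` collapses every tree to its bootstrap mean, so forest
  predictions converge to the (bootstrap-averaged) global mean — a tested
  invariant.
* Regression predictions are convex combinations of training outcomes and
  never leave $[\min y, \max y]$; multiclass rows are renormalization-free
  by construction (terminal frequencies already sum to 1).
* A constant machine column makes COBRA's $\varepsilon$ grid degenerate; the
  calibrator warns and returns the smallest grid value.
* Wilcoxon with all-zero differences returns $p = 1$ with a warning;
  constant rank-test rows contribute midranks.

## Limitations

The engine is a plain bagged-CART forest: no survival outcomes, importance
measures, proximities, case weights, or parallel tree growth; categorical
features are handled as integer codes split as ordered values. These are
deliberate non-goals. Benchmark runtimes are dominated by the $D + 1$
forests per fit; the shipped acceptance report scales the replication count
down (20 replications, test sets of 2500) to stay within a desk-scale time
budget and documents the wider Monte-Carlo error this implies.
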