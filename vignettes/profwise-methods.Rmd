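---
title: "Hybrid LASSO/mRMR selection with rank-based weighting: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid LASSO/mRMR selection with rank-based weighting: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(profwise)
```

## The problem

High-dimensional proteomic panels measure thousands of protein markers on
small patient cohorts (typically 65–110 samples against 7,000–9,000
markers). For a clinically meaningful biomarker panel — for example, serum
markers that track MGMT promoter methylation status, or a protein's
expression level — one wants the *smallest* marker subset whose
cross-validated predictive performance is best. Any single feature-selection
method is unstable at this sample size: which markers it picks fluctuates
from fold to fold, and filter and embedded methods disagree systematically.

`profwise` implements an ensemble answer: run two complementary selectors —
a filter (greedy mRMR) and an embedded method (LASSO) — inside every fold of
a stratified cross-validation, convert the per-fold selections into integer
feature weights under rank-based method weights, and sweep a minimum-weight
threshold to obtain nested candidate subsets, choosing the one with the best
mean CV score and, among ties, the fewest features.

## The procedure

Given a preprocessed samples × features matrix and a target:

1. **Fold plan.** Stratified 5-fold CV for binary targets: within each
   class, samples are shuffled and dealt round-robin, so per-fold class
   counts deviate from the proportional share by at most one sample.
   Continuous targets (or cohorts with unknown-status patients) get plain
   shuffled folds, optionally stratified on an auxiliary status vector.
2. **Per-fold selection.** On each fold's training rows, run
   - greedy mRMR: pick first the feature with maximal relevance
     \(I(Y, X_i)\), then repeatedly the feature maximizing
     \(I(Y, X_i) - \frac{1}{|S|}\sum_{X_s \in S} I(X_s, X_i)\),
     for `n_select` picks;
   - LASSO: fit an L1-penalized linear (regression) or logistic
     (classification) model on internally standardized features and keep
     the features with non-zero coefficients.
3. **Weight accumulation.** Under method weights \((w_{lasso}, w_{mrmr})\),
   each feature accumulates
   \(\sum_{folds} [\, w_{lasso}\mathbb{1}(f \in L) + w_{mrmr}\mathbb{1}(f \in M) \,]\).
   Only the two rank-based assignments \((1,2)\) and \((2,1)\) are
   enumerated — the better-performing selector gets the higher rank, and
   trying both makes the choice empirical. With 5 folds the maximum
   attainable weight is \(5 \times 3 = 15\).
4. **Threshold sweep.** For every \(k\) from 1 to the maximum observed
   weight, the candidate subset \(\{f : w(f) \ge k\}\) is scored by the
   fixed model zoo — mean fold accuracy (classification: SVM, LR, KNN, RF,
   AdaBoost) or mean fold MSE (regression: SVR, RF). Subsets are nested in
   \(k\); identical consecutive subsets reuse one evaluation.
5. **Best subset.** The best (k, model) cell maximizes accuracy or
   minimizes MSE; ties go to fewer features, then smaller \(k\), then the
   fixed model order, then assignment order.

## Estimators and tunable parameters

* **mRMR relevance/redundancy** (`mrmr_config`). Default: mutual
  information in nats, with continuous variables discretized into
  `mi_bins = 10` equal-frequency bins from average ranks (a binary target
  is used as-is). MI is the canonical mRMR quantity; equal-frequency
  binning is scale-invariant and robust to heavy tails, and 10 bins keeps
  \(\ge 6\) samples per bin at the cohort sizes this package targets. An
  `f_statistic` estimator (ANOVA/regression F for relevance, absolute
  Pearson correlation for redundancy) is offered as a faster alternative.
  Relevance and redundancy scores live at 12 significant digits, so
  mathematically equal scores (two features with identical contingency
  tables, say) compare exactly equal regardless of floating-point
  summation order; remaining ties in the greedy score break by ascending
  feature ID — determinism with no hidden state.
* **`n_select`** (per-fold mRMR picks, default 50). The prior work this
  protocol descends from does not publish its per-fold count; 50 is large
  enough that genuinely informative markers are not crowded out at
  \(p \sim 10^3\)–\(10^4\), yet small enough that the k = 1 union stays
  reviewable. It is deliberately configurable.
* **LASSO penalty** (`lasso_config`). Conventions are fixed once: for the
  linear objective, `penalty` is the \(\lambda\) of
  \(\frac{1}{2n}\|y - X\beta\|^2_2 + \lambda\|\beta\|_1\) on standardized
  predictors, so the all-zero threshold is exactly
  \(\max_j |x_j^\top y|/n\); for the logistic objective, `penalty` is an
  inverse strength \(C\) (glmnet \(\lambda = 1/(nC)\)), so the default
  `penalty = 1` mirrors the \(C = 1\) convention used elsewhere in the
  model zoo. The regression default of 0.1 was chosen once as a moderate
  value on standardized data: strong predictors pass, and the weighting
  stage is what filters residual noise. Coefficients count as selected
  above `nonzero_tol = 1e-10`.
* **Model zoo** (`model_config`) — fixed hyperparameters, every stochastic
  fit seeded 0: SVM (RBF, C = 1, gamma \(= 1/(p\,\mathrm{Var}(X))\), the
  "scale" convention), logistic regression (L2, C = 1, via ridge glmnet at
  \(\lambda = 1/n\)), KNN (k = 5, Euclidean — Minkowski with p = 2 —
  uniform votes), random forest (100 trees, Gini), and AdaBoost (real/
  SAMME.R boosting over depth-1 rpart stumps, 50 rounds, learning rate 1,
  implemented in-package). Regression: \(\epsilon\)-SVR (RBF, C = 1,
  \(\epsilon = 0.1\), scale gamma) and a 100-tree RF regressor.

## Numerical and degenerate-input choices

* Missing values in input tables are a **hard error** with coordinates —
  silent imputation would change selection results invisibly.
* Constant features are dropped (with a warning) during z-scoring; during
  selection they carry zero relevance (a single discretization bin gives
  exactly zero MI) and are never selected by LASSO (zero variance excludes
  them from standardization).
* Models receive features standardized **per fold** on training rows only
  (fit on train, apply to test), avoiding leakage; whether the original
  protocol standardized globally is not stated, so the defensible default
  was chosen.
* If a candidate subset has no training variance at all, every model
  degrades to its intercept: the majority class, or the training mean.
* Evaluation folds **reuse the selection folds** by default, reproducing
  the published single-CV protocol; the resulting scores are therefore
  model-selection criteria, not unbiased generalization estimates. A
  `nested_evaluation` switch re-splits folds (seed + 1) for
  bias-controlled scoring.
* Reports are byte-deterministic: numbers are written with round-trip
  precision, JSON without rounding, and no timestamps enter any artifact.
  Stage timings go to the console only.

## What the synthetic generator emulates — and what it does not

`synthetic_spec()` mirrors the structure of the cohorts this method is
aimed at: ~65–110 samples, thousands of positive RFU-like intensities (via
`rfu_like()`) or already-normalized values, mild class imbalance (default
positive fraction 27/65), a small planted informative set with a
between-class shift or regression slope in sd units, and correlated
redundant copies of each informative marker — the analogue of multiple
aptamers per protein, sharing a gene symbol, which is what exercises
mRMR's redundancy penalty. The default scenario (n = 100, p = 1000, 10
informative groups with 2 copies each at \(\rho = 0.8\), effect 1.5 sd)
keeps a full run to desk scale (a few minutes on one CPU) rather than
mimicking a 7k-marker panel.

It does **not** model realistic proteome covariance blocks, batch or plate
effects, assay floor/ceiling censoring, or heavy-tailed biological
variation. Passing tests therefore demonstrate that the algorithm recovers
planted, linearly expressed signal under Gaussian noise with redundancy —
not that any particular clinical panel will validate.

## Known limitations

* Greedy mRMR is \(O(\text{n\_select} \times p)\) MI evaluations per fold;
  at \(p \sim 10^4\) expect minutes per fold in pure R.
* The reused-folds default overstates absolute accuracy/MSE; treat the
  sweep scores as relative rankings unless `nested_evaluation` is on.
* Only two selectors and the two rank assignments \(\{1,2\}\) are
  supported by design; continuous weights or larger ensembles are out of
  scope.
* Binary targets only (plus a continuous regression mode); no multi-class
  support.

## Problem sizes used in the shipped checks

Unit and property tests run on instances up to n = 60, p = 150; the
end-to-end recovery check runs the default n = 100, p = 1000 scenario; the
chance-level null control runs 20 generator seeds at n = 40, p = 100. The
acceptance script (`scripts/acceptance.R`) re-runs the default
classification scenario and an n = 100, p = 500 regression scenario from
scratch under the seed it is given.
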