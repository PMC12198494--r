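---
title: "Exact Wasserstein classification: model, assumptions and design choices"
author: "habic package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exact Wasserstein classification: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(habic)
```

## The model

`habic` addresses binary classification when samples are few and
variables are many and collinear — the geometry typical of bulk and
single-cell expression matrices. Instead of measuring pointwise
(Euclidean) distances between samples, it compares the two
class-conditional *distributions* with the 1-Wasserstein (Earth-Mover)
distance and uses the function that realizes that distance as the
decision function.

For balanced training samples $x_1,\dots,x_n$ (class 0) and
$y_1,\dots,y_n$ (class 1), the Kantorovich–Rubinstein dual of the
1-Wasserstein distance between the empirical measures is

$$
W_1(\hat P_x, \hat P_y)
 = \sup_{\lVert g\rVert_L \le 1}
   \frac1n \sum_i g(x_i) - \frac1n \sum_i g(y_i),
$$

a supremum over 1-Lipschitz functions. A maximizer $\hat g$ — the *KR
optimizer* — is the 1-Lipschitz function that best separates the two
empirical distributions in mean, and the classifier is simply
$\hat f(t) = \mathbf 1\{\hat g(t) > \alpha\}$ mapped onto the class
labels.

### Exact recovery of the optimizer

The discrete problem is a linear sum assignment: with cost matrix
$c_{ij} = \lVert x_i - y_j \rVert_q$,

$$
n\,W_1 = \min_{\pi \in S_n} \sum_i c_{i,\pi(i)}
       = \max_{\psi_i + \phi_j \le c_{ij}} \sum_i \psi_i + \sum_j \phi_j .
$$

The package solves this with a primal-dual Hungarian algorithm
(shortest augmenting paths with potentials, O(n³), implemented in C++)
that returns both the optimal pairing and the dual variables
$\psi, \phi$. Three certificates are checked numerically after every
solve — dual feasibility, complementary slackness on assigned pairs,
and a zero duality gap — at an absolute tolerance of
$10^{-8}\max(1, \max_{ij} c_{ij})$, appropriate for double-precision
sums of this size. Dual optima are not unique (adding a constant to
$\psi$ and subtracting it from $\phi$ preserves optimality), so nothing
downstream depends on particular potential values, only on the
certified contracts; tests follow the same rule.

On the support the optimizer is fixed by
$\hat g(x_i) = \psi_i$, $\hat g(y_j) = -\phi_j$. Two one-sided
extensions exist off the support,
$\hat g_1(t) = -\max_j\{\phi_j - \lVert t - y_j\rVert_q\}$ and
$\hat g_2(t) = \max_i\{\psi_i - \lVert x_i - t\rVert_q\}$, each
1-Lipschitz and each interpolating the potentials. Using either alone
bases every score only on distances to one class's support; the package
scores with their average, which keeps the Lipschitz bound, still
interpolates the potentials, and uses the distances to all known points
equitably — in practice a more robust decision surface.

### Ground metric

The Minkowski order $q$ of the ground metric is a tunable (default
$q = 1$, Manhattan). Low orders are least affected by
high-dimensional distance concentration, and $q=1$ is the
best-performing choice on expression-like data; $q = 2$ makes the
ground metric rotation invariant, which is what makes a full-rank PCA
projection exactly prediction-preserving (a property the test suite
uses as an oracle).

### Decision threshold and orientation

By construction $\tfrac1n\sum_i \hat g(x_i) - \tfrac1n\sum_i \hat
g(y_i) = W_1 \ge 0$, so class 0 scores high on the training set. To
make the rule independent of which class happens to be coded first, the
orientation (which side of $\alpha$ maps to which label) is learned
from the training score means rather than hard-wired. The default
$\alpha$ is the midpoint of the two class score means ("100%
aggregation"); trimming to the top/bottom $k$ or $k\%$ of scores is
available to blunt outliers, as is a criterion-optimizing family
(accuracy, Matthews correlation, or distance to the ideal ROC corner)
evaluated on an internal stratified 75/25 split — the held-out fraction
is a configuration knob since no canonical value exists. The optimizer
fitted on the 75% side is kept as the model, so the chosen $\alpha$
stays attached to the score distribution that selected it. Scores
exactly at $\alpha$ go to the low-score class, a documented tie rule.

### Balancing

The assignment couples observations one to one, so training classes
must be exactly equal in size. Unbalanced training data are balanced by
random undersampling of the majority class (without replacement),
deterministic given the seed; this is standard practice to avoid
majority-class bias and is applied inside every cross-validation fold,
never to test data.

## Regularized variants

Two families trade some of the naive model's capacity for stability in
very high dimension:

* **Reduction** (`redPCA`, `redPLS`): project onto the leading PCA or
  PLS-DA components (fitted on training data only; centering, no
  scaling — scaling is a knob, off by default since expression inputs
  are typically already on a common scale) and fit the naive classifier
  in the reduced space. The component count defaults to the knee of the
  PCA cumulative explained-variance curve, located as the point of
  maximum perpendicular distance to the chord joining the curve's
  endpoints; an exactly linear curve has no knee and yields 1. The same
  PCA-derived count is used for PLS-DA, whose supervised components are
  preferable when reduction serves discrimination.
* **Bagging** (`bagSTD`, `bagRF`, `bagPLS`): B = 100 naive classifiers,
  each fitted on a stratified bootstrap (n/2 draws with replacement per
  class, preserving the exact balance the assignment needs) and a
  random draw of $\lfloor\sqrt p\rfloor$ features — the standard bagging
  draw size, configurable via `mtry`. The RF/PLS flavours rank the
  drawn features by random-forest impurity importance (a
  default-parameter forest of 100 trees) or by absolute PLS-DA
  regression coefficients (2 components by default) and keep only the
  top `n_keep = 3` — the lowest filter size, which is also the
  best-performing one — or the smallest prefix holding 70% of the total
  importance. Prediction is by majority vote; exact vote ties are
  broken by the sign of the summed member margins.

## The synthetic benchmark generator

`generate_classification()` produces the controlled scenarios used to
characterize the classifier: 700 observations × 10000 variables by
default, with a chosen number of *informative* variables (class
clusters are standard Gaussians at distinct vertices of a hypercube of
side `2 * class_sep` in the informative subspace, mixed by a random
uniform(−1,1) covariance transform), *redundant* variables (random
linear combinations of the informative block — pure collinearity), and
independent standard-normal *noise* for the remainder. Classes are
exactly balanced, generation is deterministic given the seed, and the
default geometry (`class_sep = 1`, one cluster per class, no label
noise) is the difficulty at which the benchmark AUC ranges are
calibrated. Holding the cluster geometry fixed while increasing the
number of informative variables spreads the same separation over more
coordinates, so the signal per variable falls — the property that makes
the 5000-informative scenarios much harder than the 100-informative
ones, mirroring transcriptomics, where many genes share information.

What the generator does *not* emulate: count marginals (negative
binomial, dropout), batch effects, gene-level correlation structure of
real cohorts. Passing benchmarks here therefore demonstrates the
transport machinery and its statistical behaviour under controlled
collinearity and signal dilution, not performance on any particular
real cohort.

## Evaluation protocols

`habic_cv()` implements stratified 5-fold cross-validation (the default
for the synthetic benchmarks) and a repeated stratified 70/30 holdout
(5 repeats by default); both report per-split ROC AUC and MCC with
mean ± sd recomputed exactly from the per-split values. AUC is the
Mann–Whitney probability that a random positive outscores a random
negative, ties counting one half, computed from continuous decision
margins so it is invariant to any strictly increasing rescaling of the
scores. MCC summarizes the confusion matrix robustly under class
imbalance; a zero marginal (e.g. a constant predictor) returns 0 by the
as-good-as-random convention.

## Numerical choices and degenerate inputs

* Dual certificates at relative tolerance 1e−8 (scaled by the largest
  cost); all arithmetic in double precision.
* Multiple optimal assignments: any optimal permutation is acceptable;
  the solver is deterministic for identical input.
* Batch scoring computes query × support distance blocks in chunks
  (`chunk_size = 256` queries by default) to bound memory at
  10^4-feature scale.
* One sample per class is allowed but flagged degenerate; identical
  scores in both classes yield a degenerate threshold with a warning.
* Constant feature columns receive zero PLS-DA importance rather than
  erroring; zero-variance data make the PCA elbow an error.
* Requested component counts above the data rank are clipped with a
  warning; `n_keep` above the feature draw likewise.
* All stochastic steps (balancing, folds, bootstraps, feature draws)
  derive child seeds from one master seed, so every fit, ensemble and
  report is exactly reproducible.

## Problem sizes used in the shipped checks

The package's own benchmark checks run the full-scale design — 700 ×
10000 synthetic scenarios under stratified 5-fold cross-validation,
with the negative control averaged over five generator seeds (a solve
at this scale takes a few seconds per fold on one core: the assignment
depends on the number of observations, not variables, which is what
makes the exact method practical for transcriptomics). Unit and
property tests use small instances (n ≤ 60, p ≤ 60) where brute-force
enumeration over all permutations, hand evaluation, and closed-form
identities serve as independent oracles.

## Known limitations

* Binary problems only; multiclass tasks must be reduced to pairs.
* Exact balance is required, so information in discarded
  majority-class samples is unused (bagging recovers some of it through
  resampling).
* Scores are not calibrated probabilities.
* No built-in variable importance for the naive model: the optimizer
  is defined over all 1-Lipschitz functions, not coordinates.
  Leave-one-feature-out retraining is the available (expensive) route.
* The training-score distribution separates strongly even on null data
  in very high dimension (overfitting of the empirical W1); honest
  assessment must come from held-out data, which is why all shipped
  figures of merit are cross-validated.
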