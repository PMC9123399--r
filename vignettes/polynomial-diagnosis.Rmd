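---
title: "Polynomial feature networks and attention-reweighted boosting for imbalanced clinical tables"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Polynomial feature networks and attention-reweighted boosting for imbalanced clinical tables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nlpnn)
```

## The problem this package addresses

Clinical tabular datasets for chronic-disease screening are typically small
(hundreds to a few thousand records), and two properties make them hard for
off-the-shelf classifiers. First, *feature hiding*: the recorded covariates
(heart rate, BMI, lab values) are rarely decision-relevant on their own —
the discriminating signal lives in interactions and powers of them. Second,
*class imbalance*: sick cases are scarce relative to healthy ones (ratios
up to roughly 1:13 in public registries), so a classifier trained for plain
accuracy learns to wave the minority through, and a missed sick case is far
costlier than a false alarm.

The package implements two estimators that target these two problems
directly:

* **NLPNN** (network-limited polynomial neural network): a feedforward
  feature constructor whose nodes are polynomial functions of the input,
  with the network's depth and per-layer width capped in advance, topped by
  an L2-regularized hinge-loss linear readout.
* **AEPNN** (attention-empowered NLPNN): a boosting ensemble of NLPNNs in
  which "attention" is a multiplicative sample-weight distribution that is
  shifted onto misdiagnosed cases after each round, plus per-classifier
  vote weights.

## The polynomial feature network

Write the training data as $X \in \mathbb{R}^{n \times d}$ with labels
$y \in \{-1, +1\}^n$ (+1 = sick). Every polynomial of total degree at most
$M$, evaluated on the $n$ training points, is a vector in $\mathbb{R}^n$;
the set of such vectors is a linear subspace. The network builds a basis of
that subspace layer by layer:

1. **Layer 1** is a partial orthogonal basis of the augmented matrix
   $[\mathbf{1}\; X]$, obtained by singular value decomposition and
   truncated to the leading $\min(\omega_1, \mathrm{rank})$ left singular
   vectors. These columns span the affine (degree-1) functions' values.
2. **Layer $m$** starts from the candidate matrix
   $\tilde F^m = [\,F^{m-1}_i \circ F^1_j\,]$ of all Hadamard (elementwise)
   products of a previous-layer column with a first-layer column, ordered
   $i$-major/$j$-minor. Because any degree-$m$ polynomial decomposes into
   degree-1 times degree-$(m-1)$ terms plus lower order, these candidates
   extend the span to all degree-$m$ values.
3. A greedy **orthogonal least squares** pass picks at most $\omega_m$
   candidates: at each step the candidate whose component orthogonal to
   everything already selected has the largest squared correlation with
   $y$ wins (ties to the lowest index). Candidates whose orthogonal
   residual norm falls below `rank_tol * sqrt(n)` add no numerical rank and
   are skipped; if nothing remains, construction stops early.
4. Each stored column is the *original* candidate rescaled to norm
   $\sqrt n$ ($W = \sqrt n / \|\tilde F^m_s\|$); orthogonalized copies are
   used only inside the selection. The construction record
   $(i(s), j(s), W_s)$ — plus the layer-1 projection — is all that is
   needed to replay the transform on new samples.

With the width caps lifted, the concatenated stack spans exactly the
degree-$\le M$ monomial design matrix (the test suite verifies the mutual
projection residuals at $d = 3$, $M = 3$). With the default caps
$\Omega = (d+1, \dots, d+1)$ the construction is a *budgeted* basis: it
keeps the $d+1$ interaction directions per layer most correlated with the
diagnosis, which is what controls overfitting on small samples.

### Supervised versus unsupervised selection

The greedy criterion could either maximize span growth (unsupervised) or
explained label variance (supervised). We use the supervised criterion:
the point of the deeper layers is to surface *diagnosis-relevant*
interactions, and on width-capped networks the label-driven choice is the
one that makes the budget count. This is a genuine design decision; the
unsupervised alternative changes only `select_layer_columns`.

## The readout

For each depth cutoff $m$ the package fits a linear classifier $\nu_m$ on
the features $[F^1 \cdots F^m]$ by minimizing

$$ \sum_{i=1}^n w_i \, \max(0,\, 1 - y_i (b + f_i \cdot \nu_m))
   \; + \; \lambda_m \|\nu_m\|_2 , $$

with $w_i = 1/n$ unless the boosting wrapper supplies sample weights. Note
the penalty is the norm, not the squared norm, and the intercept $b$ is
not penalized (layer 1 usually contains the constant direction, but an
explicit intercept is kept for the rank-deficient corner cases).

The $(m, \lambda)$ pair is chosen on a stratified 20% validation carve-out
of the training data (`validation_fraction`), by 0-1 accuracy (weighted
accuracy when sample weights are present); ties prefer the shallower $m$,
then the larger $\lambda$. The winner is refit on the full training data.
The default grid is $\Lambda = \{10^{-3}, \dots, 10^{1}\}$.

### Optimization

The readout is fit by seeded mini-batch subgradient descent with a staged
schedule: 16 stages of constant step $\eta_0 2^{-(s-1)}$, Polyak-Ruppert
averaging within each stage, an exact line search over the scalar multiple
of each stage average (the objective is convex along a ray, and norm
overshoot dominates the error on near-separable problems), and the best
candidate by full-data objective returned. Two details matter:

* the initial step is $\eta_0 = \max(0.5,\, 0.01/\lambda)$ — for weak
  regularization the optimum's norm grows like $1/\lambda$ and the iterate
  must travel correspondingly far before the fine stages polish;
* at least 48\,000 updates are run regardless of `epochs`, so that
  small-$n$ problems (where an epoch is two batches) are not
  under-optimized.

`fit_readout_exact()` is a deterministic reference solver for small
instances: the hinge and norm kinks are Huber-smoothed with a continuation
schedule ($\delta = 10^{-2} \to 10^{-8}$) and each stage solved by BFGS
with analytic gradients; the smoothing gap is bounded by
$\delta(1/2 + \lambda)$. The test suite holds the SGD objective within 1%
of this reference on a panel of 20 random instances with $n \le 50$,
$p \le 10$.

### A note on exact training separation

Regularized hinge minimization does *not* reproduce the training labels
exactly whenever some samples sit arbitrarily close to the decision
boundary: separating a point at signed distance $\gamma$ costs norm
$\sim 1/\gamma$, i.e. penalty $\lambda/\gamma$, while misclassifying it
costs at most a few times $1/n$. Continuous feature distributions put
samples at distance $O(1/n)$ from the boundary, so perfect training
accuracy is provably not the optimum there — for any $\lambda$ in the
default grid. Exact-recovery demonstrations in the tests therefore use
margin constructions (the XOR-style grid, affine truths with a margin),
where separation *is* the optimum; on boundary-dense Gaussian samples the
relevant yardstick is held-out accuracy.

## Attention-empowered boosting

AEPNN runs `L_max` (default 10, matching the iteration budget used in the
source experiments) rounds of exponential-loss boosting over NLPNN base
learners:

1. start from uniform weights $\mathcal D_1 = 1/n$;
2. fit an NLPNN with the current weights entering the hinge loss (loss
   weighting, not resampling — deterministic and testable);
3. measure the weighted training error $\epsilon_l$, convert it to the
   vote weight $\alpha_l = \tfrac12 \ln((1-\epsilon_l)/\epsilon_l)$ (the
   minimizer of the exponential loss);
4. update $\mathcal D_{l+1} \propto \mathcal D_l e^{-\alpha_l y h_l(x)}$ —
   after which $h_l$'s weighted error is exactly $1/2$, so the next round
   must find something new.

Edge cases follow standard boosting practice: a perfect round
($\epsilon = 0$) is kept with $\alpha$ capped at the value for
$\epsilon_0 = 1/(2n)$ and training stops; a round at or worse than chance
($\epsilon \ge 0.5$) is discarded and training stops (an error if it is
the first round). $\epsilon_l$ is measured on the weighted *training*
sample — that is the quantity the exponential-loss argument concerns —
while the per-round history records accuracy/recall/F1/G-mean of the
truncated ensemble on a held-out set (an explicit `val_table`, or an
internal stratified 20% carve).

`select_iterations()` picks the round maximizing *recall growth minus
accuracy drop*, both relative to round 1. When round-1 recall is zero the
growth denominator is floored at $1/(2 n_{pos})$ to stay finite — a recall
climbing off zero then shows as a very large growth rate, which is the
intended behavior for imbalance repair.

## Metrics

`metric_report()` computes accuracy, specificity, precision, recall,
F1 and G-mean $=\sqrt{\text{recall} \cdot \text{specificity}}$ from the
confusion matrix with +1 as the sick class, and a midrank (Mann-Whitney)
AUC from decision scores. F1 is computed as $2TP/(2TP+FP+FN)$, which
coincides with both the harmonic-mean form and the $2TP/(N+TP-TN)$ form
whenever they are defined. A metric whose denominator is zero is reported
as `NA` (missing), never as an exception or a silent zero.

## Data protocol

`load_csv()` implements the experimental protocol: missing cells (empty,
`"?"`, `"NA"`, `"nan"`; configurable) are filled with zeros, and the label
column is mapped to +1 (the configured positive value) and -1 (everything
else). `split_table()` performs the seeded stratified 80/20 train/test
split, holding out `round(class_count * test_fraction)` per class so the
class ratio is maintained. Zero-fill is the only imputation offered; a
z-score `standardize()` exists solely for comparisons against scale-
sensitive baselines and is never applied inside NLPNN, whose SVD layer
adapts to feature scale.

## The synthetic generator

`synth_generate()` produces the data every test runs on: features drawn
i.i.d. standard normal, a hidden polynomial with standard-normal
coefficients over all monomials of total degree $\le$ `degree`, and labels
$\mathrm{sign}(p(x) - \tau)$ where $\tau$ is calibrated by bisection (60
steps, on a 20 000-point probe sample) so the positive fraction is within
10% relative of $1/(1+r)$ for the requested imbalance $r$. Optional label
noise flips labels independently; optional missingness masks feature cells
(stored as `NA` to exercise the zero-fill path). Everything derives from
one seed.

What it emulates: polynomial decision boundaries (feature hiding), the
imbalance ratios of the public chronic-disease benchmarks (1:0.24 up to
1:12.78), label noise, missing values. What it does not emulate: discrete
and bounded clinical covariates, correlated features, subpopulation
structure, or informative missingness. Passing tests on this generator
demonstrate the mechanics of the estimators under controlled conditions;
they do not certify performance on any particular clinical dataset.

## Study problem sizes and the imbalance experiment

The test and acceptance computations use desk-scale sizes chosen so each
check isolates one property: $n = 40$, $d = 3$, $M = 3$ for the span
oracle (just above the 20 monomials it must span); $n = 400$, $d = 2$ for
degree-2 recovery; $n = 200$, $d = 3$ with exact readouts for depth
monotonicity.

The imbalance study mirrors the shape of the feature-rich diabetes
registries that motivate the boosting wrapper: $n = 2000$, $d = 40$
features, a degree-2 truth, 2% label noise, imbalance 1:12, default
two-layer width-$(d{+}1)$ networks, `L_max = 10`. The width cap is the
operative ingredient: with 861 candidate interactions and only 41 slots
per layer, a single network cannot hold all the structure, the
accuracy-optimal base learner concentrates on the majority class, and the
reweighted rounds recover different feature subsets — which is exactly the
regime where boosting repairs recall. On low-dimensional smooth data the
base learner is already near-optimal and boosting (correctly) has nothing
to add; the ensemble then ties the single network rather than beating it.

## Numerical choices

* Rank decisions (SVD truncation, OLS dependence) use a relative tolerance
  of $10^{-8}$ (`rank_tol`).
* SVD factors are sign-canonicalized (largest-magnitude entry of each
  right singular vector made positive) so layer 1 is reproducible across
  platforms.
* `sign(0) = +1` everywhere: readout predictions, ensemble votes,
  generator labels.
* OLS ties break to the lowest candidate index; validation ties prefer
  shallower, more regularized readouts.
* Model files are JSON with doubles encoded as `%.17g` strings, so a
  save/load round trip reproduces predictions bit-for-bit.
* Single-class training labels yield a constant classifier rather than an
  error.

## Limitations

Binary classification only; dense numeric features only (categorical
variables must be encoded upstream); zero-fill is the only built-in
missing-data treatment, mirroring the experimental protocol rather than
best imputation practice; no probability calibration of scores; the
per-round NLPNN refits make AEPNN roughly `L_max` times the cost of a
single network.
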