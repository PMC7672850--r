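---
title: "Multi-view Hessian-regularized symmetric NMF: model and methods"
author: "mhsnmf package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-view Hessian-regularized symmetric NMF: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mhsnmf)
```

# The problem

Modern microbiome and multi-omics studies describe one cohort of samples
through several heterogeneous feature matrices — e.g. a phylogenetic
relative-abundance profile, a metabolic-pathway profile and a transporter
profile over the same body-site samples. Each *view* carries partial,
noisy information about the same underlying group structure. This package
clusters such cohorts by fusing the views into a single consensus
factorization, and classifies new samples in the learned consensus space.

# The model

For each view $v$ a symmetric nonnegative sample–sample affinity $A^v \in
\mathbb{R}_+^{n\times n}$ is built (below). Symmetric NMF (SNMF)
approximates one affinity as $A \approx HH^\top$ with $H \in
\mathbb{R}_+^{n\times k}$; the row argmax of $H$ is a $k$-way clustering.
The multi-view model couples the per-view factors $H^v$ through a
consensus factor $H^*$ and penalizes consensus "curviness" along each
view's data manifold via Hessian energy operators $B^v$:

$$
\min_{H^v, H^* \ge 0,\ \alpha \in \Delta}
\sum_v \lVert A^v - H^v (H^v)^\top \rVert_F^2
+ \gamma \sum_v \lVert H^v Q^v - H^* \rVert_F^2
+ \beta\, \mathrm{tr}\!\Big( (H^*)^\top \big(\textstyle\sum_v (\alpha^v)^r B^v\big) H^* \Big),
$$

where $Q^v = \mathrm{Diag}(1/\mathbf{1}^\top H^v_{\cdot 1}, \ldots)$
rescales each view's factor to unit column sums so clustering solutions
are comparable before coupling, $\gamma \ge 0$ weighs the coupling,
$\beta \ge 0$ the smoothness penalty, and the simplex-constrained view
weights $\alpha^v$ are learned. The exponent $r > 1$ is the standard
multi-graph smoothing trick: with a linear weighting the optimum would put
all weight on the single smoothest view; with $(\alpha^v)^r$ every view
contributes and the weights have the closed form

$$
\alpha^v = \frac{(1/t_v)^{1/(r-1)}}{\sum_u (1/t_u)^{1/(r-1)}},
\qquad t_v = \mathrm{tr}\big((H^*)^\top B^v H^*\big).
$$

We read the exponent as $1/(r-1)$ (the convention in multi-graph weight
learning); only with that reading is the closed form the exact minimizer,
which the test suite verifies against grid search (2 views) and a
constrained numerical minimizer (3 views). Default $r = 2$.

## Affinity graphs

Per view the pipeline is kernel → kNN sparsification → symmetric
normalization:

* **Gaussian kernel with local scaling** (default):
  $W_{ij} = \exp(-\lVert V_i - V_j\rVert^2 / \sigma_i\sigma_j)$, $W_{ii}=0$,
  with $\sigma_i$ the Euclidean distance to the `scaleIndex`-th neighbour
  (default 7). Local scaling adapts the bandwidth to density differences.
  A **cosine kernel** is available for text-like sparse views.
* **kNN sparsification** keeps $W_{ij}$ iff $i \in N(j)$ *or*
  $j \in N(i)$ (union rule, so the graph stays symmetric); default
  `knn = 12`. Ties at the neighbourhood boundary break by ascending
  sample index for reproducibility. $\sigma_i$ is computed on the full
  distance matrix, before sparsification.
* **Normalization** $A = D^{-1/2} W D^{-1/2}$ with $D$ the row-sum
  diagonal of the *sparsified* $W$; the spectral radius of $A$ is then at
  most 1. Isolated nodes (zero row sum) raise an error naming the
  offending indices.

## Hessian energy

$B^v$ is an $n\times n$ symmetric positive semidefinite operator whose
quadratic form $f^\top B f$ estimates the integrated squared second
derivative of a function $f$ sampled on the view's manifold. Per sample:
take its `knnH` nearest neighbours (default 30; the center itself is
excluded — after centering it would contribute a zero row), center them on
the sample, fit a $d$-dimensional tangent frame from the first $d$ left
singular vectors, build the design matrix
$[\,\mathbf{1} \mid U \mid \text{squares and cross products of } U\,]$
(quadratic block in lexicographic pair order), orthonormalize by modified
Gram–Schmidt with one re-orthogonalization pass (columns below
$10^{-10}$ are dropped with a warning), and accumulate the Gram matrix of
the transposed quadratic block into $B$ at the neighbours' indices.

The tangent dimension $d$ is not dictated by the model; it is exposed
with default $d = 2$, the smallest nontrivial manifold dimension — the
solver's behaviour is insensitive to moderate changes of the Hessian
neighbourhood settings, and only the span of the quadratic block matters
after orthogonalization, so the column order convention is free. The
tests verify the defining properties rather than any particular basis:
$B$ is PSD, annihilates functions affine in the intrinsic coordinates of
a planar fixture, matches an index-level brute-force accumulation, and
its bottom eigenspace on a swiss-roll fixture reproduces the isometric
(arc-length) coordinates. Note the intrinsic coordinates of a curved
manifold are its *isometric* ones: on a spiral the null space is affine
in arc length, not in the winding angle.

## Updates and damping

Holding the other blocks fixed, the KKT conditions give multiplicative
updates. Per view:

$$
H_{ic} \leftarrow H_{ic}\left(\tfrac12 +
\frac{2(AH)_{ic} + \gamma (H^* Q)_{ic}}
     {2\,(2(HH^\top H)_{ic} + \gamma (HQ^2)_{ic}) + \varepsilon}\right).
$$

The ratio alone is the textbook rule; we apply the $\tfrac12$-damped form
standard in symmetric NMF, which has the same fixed points but makes the
objective empirically nonincreasing — the undamped ratio measurably
oscillates on dense symmetric inputs (relative objective increases of
order $10^{-2}$ on about half the steps), while the damped rule is
monotone to $\sim 10^{-12}$ across all test fixtures. For the consensus,
with $B = \sum_v (\alpha^v)^r B^v$ split into positive and negative parts
$B = B^+ - B^-$ so nonnegativity is preserved:

$$
H^*_{ij} \leftarrow H^*_{ij}
\frac{\big(\gamma \sum_v H^v Q^v + \beta B^- H^*\big)_{ij}}
     {\big(\gamma\, n_v H^* + \beta B^+ H^*\big)_{ij} + \varepsilon}.
$$

$\varepsilon = 10^{-10}$ guards every denominator. A sweep updates each
view's $H^v$ (recomputing $Q^v$ immediately, since $Q^v$ is defined by
$H^v$) followed by the consensus, then updates $\alpha$ once. The solver
stops when the relative objective change drops below `tol` (default
$10^{-6}$) or after `maxIter` (default 500) sweeps, and aborts with
diagnostics if the objective rises by more than $10^{-6}$ relative for
five consecutive sweeps.

## Initialization and cluster alignment

Each $H^v$ is initialized by NNDSVD on $A^v$: deterministic nonnegative
starting values from the leading $k$ singular pairs, with exact zeros
floored at $10^{-6}$ — multiplicative updates cannot leave an exact zero,
so some floor is required; the variant choice only perturbs the start.

The initial consensus is the mean of the column-rescaled factors
$H^vQ^v$ — *after aligning columns across views*. This alignment step is
a deliberate design choice: for well-separated clusters the normalized
graph is near block diagonal and its leading eigenvalues are degenerate,
so independently computed NNDSVD factors order their columns arbitrarily
per view. Averaging unaligned factors scrambles the consensus and the
coupling then pulls every view toward the scrambled average (observed:
accuracy at chance on a fixture the aligned solver clusters perfectly).
Views $2..n_v$ are therefore permuted to best match view 1 by a Hungarian
assignment on the cross-products of the rescaled factors. The permutation
touches only the starting point; the update rules are exactly as above.
One consequence: permuting the order of the input views permutes the
learned weights and can permute the consensus *columns* (the alignment
reference changes), leaving the induced partition unchanged — the test
suite asserts exactly that. Initial weights are uniform, $\alpha^v = 1/n_v$.

# Out-of-sample prediction

A new sample $x$ from view $i$ is summarized by a similarity vector $S$
to the $n_{tr}$ training samples, embedded by solving
$\min_{h\ge 0}\lVert S - H^* h\rVert^2 + \mathrm{reg}\,\lVert h\rVert^2$
(Lawson–Hanson nonnegative least squares on the augmented system;
deterministic; default $\mathrm{reg} = 0.1$ — the ridge only needs to
regularize near-collinear consensus columns, and the tests confirm
$\lVert h \rVert$ shrinks monotonically in it), and classified by
majority vote among the `knnClassify` = 5 nearest training rows of $H^*$
(vote ties to the smallest label, distance ties to the lowest index).
$H^*$ comes from the training fit only; nothing is refit per test sample.

The form of $S$ matters. The linear form $S = V_{tr}^\top x$ is exported
as `similarityToTraining()` and is appropriate when the training graph is
itself inner-product based (cosine views): then $S$ lives on the scale of
the trained affinities and $h$ lands near the consensus rows of the
sample's cluster. When the training graph used the locally scaled
Gaussian kernel, raw inner products are on a different scale and geometry
than the affinity the consensus explains — they are dominated by the
samples' common positive component, and the embedding degenerates toward
the largest-norm cluster (chance-level accuracy on the synthetic
fixtures). `kernelSimilarityToTraining()` is the out-of-sample analogue
of the training kernel (training bandwidths $\sigma_j$ plus a bandwidth
for $x$ from its `scaleIndex`-th nearest training sample). The holdout
protocol and the CLI therefore default to `similarity = "auto"`:
kernel-matched $S$ for Gaussian views, inner products for cosine views;
both forms can be forced.

The holdout protocol splits each class by `trainFrac` (default 0.7,
stratified; classes with fewer than 2 samples stay whole in training with
a warning), fits on the training views, and reports per-view and average
test accuracy.

# Synthetic data: the stated world

`makeMultiviewBlobs()` emulates the model's core assumption — one latent
cluster assignment observed through several views. Defaults are the
conditions exercised throughout the tests: $n = 150$ samples, $k = 3$
near-balanced clusters, 2 views, minimum latent center separation 10,
noise sd 0.5. Values the scenario leaves open were fixed once at what a
practitioner would call realistic for well-separated community types:
latent dimension 6, centers uniform on $[0, 2\cdot\text{separation}]^6$
(redrawn until the separation holds; error after 100 redraws), per-view
random Uniform(0,1) nonnegative linear maps of 30 and 40 features, and
Gaussian noise clipped at zero to keep matrices nonnegative (the
truncation slightly biases means upward; it is documented rather than
corrected). `makePlanarManifold()` supplies exact affine 2-flats for the
Hessian annihilation tests.

What the generator does **not** emulate: compositionality (no unit-sum
constraint), sparsity and zero inflation, overdispersion, and unbalanced
body-site sizes of real microbiome profiles. A green test establishes
correctness of the algorithmic machinery on separable shared-structure
data, not performance on real multi-omics cohorts.

# Numerical choices and degenerate inputs

* $\varepsilon = 10^{-10}$ in all multiplicative denominators; NNDSVD
  zero floor $10^{-6}$.
* Neighbour ties anywhere (graphs, Hessian, classification) break by
  ascending index; argmax ties by lowest column; vote ties by smallest
  label. All paths are deterministic given the seed.
* Duplicate-heavy views ($\sigma_i = 0$) and zero-norm cosine columns
  raise errors naming the offending samples; dead clusters (zero column
  sums) zero the corresponding $Q$ entry with a warning; rank-deficient
  local neighbourhoods warn and zero-pad missing tangent directions;
  degenerate quadratic basis columns are dropped at tolerance $10^{-10}$.
* Accuracy uses an exact Hungarian assignment on the confusion matrix
  (not greedy matching); NMI normalizes by $\sqrt{H(\text{pred})
  H(\text{truth})}$ with the $0/0 \to 0$ convention — one-to-one matched
  accuracy is *not* bounded below by the majority-class fraction (that
  bound belongs to many-to-one purity), which the tests reflect.

# Limitations

* Dense $O(n^2)$ matrices throughout; intended for cohorts up to a few
  thousand samples, not $10^4$+.
* Convergence of the alternating scheme is monitored, not proven; the
  divergence guard aborts rather than repairs.
* $k$ and the tangent dimension $d$ are user choices; no automatic model
  selection.
* Prediction fuses nothing at test time: each new sample is classified
  from one view's similarity vector.
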