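---
title: "Multi-graph regularized matrix completion for drug-target interaction prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-graph regularized matrix completion for drug-target interaction prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dtimc)
```

## The problem

Experimentally mapping which drugs bind which protein targets is slow and
expensive, so computational screening is used to rank candidate pairs for
validation. The chemogenomic formulation used here takes three inputs: an
`n x m` binary interaction matrix (rows drugs, columns targets; 1 = known
interaction), a drug–drug chemical structure similarity, and a target–target
sequence similarity. Known interaction networks are extremely sparse, and a
useful method must also rank pairs for *novel* drugs or targets that have no
recorded interactions at all (the cold-start settings below).

## Model

The completed interaction matrix $X$ is assumed to be low-rank — a few latent
pharmacological factors explain binding — and smooth over the drug and target
similarity graphs. `dtimc` estimates $X$ by minimizing

$$\|A \circ (M - X)\|_F^2 + \lambda \|X\|_*
  + \mu_1\,\mathrm{Tr}(X^\top L_d X) + \mu_2\,\mathrm{Tr}(X L_t X^\top),$$

where $M$ is the observed matrix, $A$ the binary observation mask,
$\|X\|_*$ the nuclear norm (the convex surrogate for rank), and $L_d, L_t$
are *combined* graph Laplacians built from five similarity measures per side:
the standard structure/sequence similarity plus four similarities derived
from the interaction profiles themselves (cosine, Pearson correlation,
Hamming, Jaccard). Because Laplacians are additive, summing the weighted
similarity matrices first and building one Laplacian from the sum is exactly
equivalent to summing per-measure Laplacians — the package exploits that
identity (and tests it).

### Optimization

The objective is split with proxies $Y \approx X$ and $Z \approx X^\top$ and
minimized by alternating block updates:

1. **X-update** — a nuclear-norm-penalized least squares against the
   observations and both proxies, solved by proximal-gradient singular value
   shrinkage: a gradient step of length $1/(2a)$ with $a = 1 + \nu_1 + \nu_2$
   followed by soft-thresholding of singular values at $\lambda/(2a)$. The
   solve is warm-started from the current $X$, so a modest inner iteration
   cap suffices.
2. **Y-update** — setting the gradient to zero gives
   $\nu_2 Y + \mu_2 Y L_t = \nu_2 X$, a Sylvester equation whose left
   coefficient is a scalar. Its closed form is
   $Y = \nu_2 X (\nu_2 I + \mu_2 L_t)^{-1}$, computed with one Cholesky
   factorization; no general Sylvester solver is needed. Note the proxy that
   multiplies the Laplacian *on the right* must couple to the operator of the
   matching dimension: $Y$ (n×m) pairs with the m×m target Laplacian and
   $Z$ (m×n) with the n×n drug Laplacian.
3. **Z-update** — the drug-side analogue,
   $Z = \nu_1 X^\top (\nu_1 I + \mu_1 L_d)^{-1}$.

Each Y/Z update minimizes its block exactly and the warm-started X-update
descends monotonically, so the recorded objective history is non-increasing
and the loop stops when its relative change falls below `tol`. With
$\mu_1 = \mu_2 = 0$ the iteration is a proximal-point wrapper around plain
nuclear norm completion and converges to the same minimizer — the test suite
verifies this reduction numerically.

### The nonnegativity projection

Interaction scores are propensities, so by default every X iterate is
projected onto the nonnegative orthant. This projection is a heuristic
restriction: combined with singular value thresholding it is not the exact
proximal operator of the constrained objective, and it can tick the recorded
objective up by around $10^{-5}$ on occasional iterations. Monotone-descent
properties are therefore stated (and tested) for the convex iteration
(`nonneg = FALSE`); in practice the projected iteration also descends at the
outer (ADMM) level on all tested problems. The projection never matters for
ranking-based metrics beyond clamping already-negative scores.

## Graph construction

For each side the five similarity matrices are combined as
$S^{COM} = \sum_i w_i S_i$ with default weights
`standard = 1, cosine = 4, correlation = 4, hamming = 1, jaccard = 4`
(Hamming carries the least predictive signal, so the other interaction
similarities are weighted four times as heavily; the standard similarity's
weight is exposed as a parameter). Then:

* **Clipping.** Cosine and correlation can be negative, but Laplacian edge
  weights must be nonnegative for positive semidefiniteness; negative
  combined entries are clipped to zero (treated as absent edges).
* **Sparsification.** A mutual p-nearest-neighbor mask keeps an edge at full
  weight if both nodes are in each other's p-NN sets, at half weight if only
  one is, and drops it otherwise (`p = 5` by default, capped at one less
  than the side's node count so small networks degrade to the full
  neighborhood). Ties in similarity are broken by ascending index so the
  mask is deterministic; a node is never its own neighbor.
* **Normalization.** The symmetric normalized Laplacian
  $D^{-1/2} L D^{-1/2}$ is used by default (eigenvalues in $[0,2]$);
  zero-degree nodes get a zero scaling entry rather than an infinity.

### Degenerate profiles

Cold-start drugs/targets have all-zero training profiles, for which cosine
(zero norm), correlation (zero variance) and Jaccard (empty union) are
formally 0/0. All three conventions map to similarity 0: a profile with no
observed interactions contributes no interaction-derived evidence, and the
graph for that node defers entirely to the structure/sequence similarity.

## Tunable parameters

| parameter | meaning | default |
|---|---|---|
| `lam` | nuclear norm weight (shrinkage strength, dimensionless) | 1 |
| `mu1`, `mu2` | drug-/target-graph regularization weights | 0.5, 0.1 |
| `nu1`, `nu2` | proxy coupling penalties of the splitting | 1, 1 |
| `p` | mutual nearest-neighbor count for sparsification | 5 |
| `weights` | per-measure similarity weights | 1,4,4,1,4 |
| `tol`, `max_iter` | outer relative-objective tolerance / cap | 1e-6, 200 |

`mu1 = 0.5, mu2 = 0.1` sit at the AUPR optimum of the benchmark parameter
surface for this model family; `grid_search()` can re-tune them per dataset
on inner validation folds (selection by mean AUPR, deterministic tie-break
by grid order).

## The synthetic generator

No public benchmark ships with the package (the gold-standard files live on
an external server), so `simulate_dti()` generates networks with exactly the
structure the method exploits, and the whole test suite runs on them:

* Drugs and targets get **positive latent factors** drawn log-normally
  around per-cluster centroids (6 drug clusters, 5 target clusters at the
  default 60×30 size; multiplicative noise sd 0.25 — tight enough that
  cluster structure, and hence the similarity graphs, carry real signal).
* The noiseless propensity matrix is $P = UV^\top / \max(UV^\top)$ — a
  monotone rescaling of the latent inner product, so $\mathrm{rank}(P)$
  equals `latent_rank` *exactly* (a rank-3 default).
* Interactions are the top `round(density * n * m)` propensities
  (15% default), then each label is independently flipped with probability
  `label_flip_rate` (5% default) to emulate annotation noise.
* Side similarities are $(1 + \cos)/2$ of the latent factors, so the graphs
  are informative about the low-rank signal without revealing it directly.

What this emulates: a clustered, low-rank interaction propensity with
consistent side information. What it does not: the extreme sparsity skew of
real gold-standard networks, hub drugs/promiscuous targets, or similarity
measurement noise that is uncorrelated with the latent factors. Passing
tests on this generator show the estimator recovers structure it is designed
for; they do not certify performance on any particular real dataset.

## Evaluation design

Three hold-out settings mirror standard practice: CVS1 masks random pairs,
CVS2 whole drug rows (novel drugs), CVS3 whole target columns (novel
targets); 5 runs of 10-fold CV is the default plan. Two design choices
matter:

* **Leak-free similarities.** Interaction-derived similarities are
  recomputed per fold from the training matrix with held-out entries zeroed
  (a `leak_free = FALSE` flag reproduces the full-matrix variant); training
  zeros are treated as observed non-interactions.
* **Per-fold metrics.** AUPR is the non-interpolated step-curve area
  (average precision) with ties ranked pessimistically — negatives ahead of
  positives at equal score; AUC is the Mann–Whitney statistic with ties
  counted one half. Metrics are computed per fold and then averaged (mean
  and sd across all folds of all runs). Folds whose test set lacks a
  positive (or negative) are skipped with a warning — unavoidable for very
  sparse networks split ten ways.

## Problem sizes

The shipped tests exercise matrices between 2×2 and 60×30 (the synthetic
benchmark size, with NR-sized 54×26 convergence checks and 20×15 oracle
comparisons); solver oracles run the inner iteration to $10^{-12}$–$10^{-14}$
relative tolerance. These sizes make every oracle comparison exact and keep
the full suite fast; the solver itself is dense-SVD based and comfortable up
to a few thousand rows/columns.

## Known limitations

* Dense SVD per inner iteration: cubic in the smaller dimension, so very
  large pharmacology networks would need a truncated-SVD backend.
* The nonnegativity projection is heuristic (see above).
* Scores are relative propensities for ranking; they are not calibrated
  interaction probabilities.
* Hyperparameter defaults were chosen for the benchmark family; new data
  should re-run `grid_search()`.
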