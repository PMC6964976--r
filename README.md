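# dtimc — drug–target interaction prediction by multi-graph regularized matrix completion

Predicting which drugs bind which protein targets is a ranking problem over
an extremely sparse binary matrix: a few hundred experimentally confirmed
interactions among tens of thousands of candidate pairs. `dtimc` completes
the partially observed interaction matrix under a low-rank prior, steered by
*multiple* drug–drug and target–target similarity graphs, and ships the
cross-validation machinery used to benchmark such methods. It is written for
computational chemogenomics practitioners: data frames in, tibbles out,
`tidy()`/`glance()`/`autoplot()` on every fitted object.

## The model

With `M` the observed drug–target matrix, `A` the observation mask, and
`L_d`, `L_t` combined graph Laplacians over drugs and targets, the estimate
solves

```
min_X  || A ∘ (M − X) ||_F²  +  λ ||X||_*
        + μ₁ Tr(Xᵀ L_d X)  +  μ₂ Tr(X L_t Xᵀ)
```

* `||X||_*` (nuclear norm, the sum of singular values) is the convex
  surrogate for rank: few latent pharmacological factors drive binding.
* Each Laplacian combines **five** similarity measures — the standard
  chemical-structure (drugs) or sequence (targets) similarity plus four
  similarities computed from interaction profiles (cosine, Pearson
  correlation, Hamming, Jaccard) — weighted, clipped to nonnegative edges,
  and sparsified to mutual p-nearest neighbors.
* The solver splits the problem with proxies `Y ≈ X`, `Z ≈ Xᵀ` (ADMM):
  a warm-started singular-value-shrinkage X-update alternates with
  closed-form Sylvester updates `Y = ν₂ X (ν₂I + μ₂L_t)⁻¹` and
  `Z = ν₁ Xᵀ (ν₁I + μ₁L_d)⁻¹`.

Setting `mu1 = mu2 = 0` gives plain nuclear-norm matrix completion
(singular value shrinkage), which doubles as the built-in baseline.

## Worked example

Everything runs on the built-in graph-consistent generator (no downloads);
`read_dti()` reads real benchmark files in the tab-delimited gold-standard
dialect interchangeably.

```r
library(dtimc)

sim <- simulate_dti(seed = 1)   # 60 drugs x 30 targets, latent rank 3
dataset_stats(sim$dataset)
#> # A tibble: 1 × 4
#>   n_drugs n_targets n_interactions sparsity
#>     <int>     <int>          <int>    <dbl>
#> 1      60        30            353    0.196

fit <- fit_dti(sim$dataset)     # defaults: lam = 1, mu1 = 0.5, mu2 = 0.1
glance(fit)
#> # A tibble: 1 × 4
#>   iterations converged objective  rank
#>        <int> <lgl>         <dbl> <int>
#> 1         14 TRUE           93.7    30

tidy(fit) |> dplyr::arrange(dplyr::desc(score)) |> head(3)
#> # A tibble: 3 × 3
#>   drug   target score
#>   <chr>  <chr>  <dbl>
#> 1 D00045 T00030 1.06
#> 2 D00045 T00005 1.02
#> 3 D00037 T00005 0.996
```

The 353 ones are the known interactions (top 15% of the latent propensities
plus 5% label noise); the fit converges in 14 alternating iterations and the
highest completion scores mark the pairs the model would send to validation
first. Held-out performance under the conventional pair-prediction split
(5 runs of 10-fold CV):

```r
plan <- make_folds(60, 30, "CVS1", k_folds = 10, n_runs = 5, seed = 2)
cv <- cross_validate(sim$dataset, mgnnm_params(), plan)
glance(cv)
#> # A tibble: 1 × 7
#>   setting n_folds n_scored aupr_mean aupr_sd auc_mean auc_sd
#>   <chr>     <int>    <int>     <dbl>   <dbl>    <dbl>  <dbl>
#> 1 CVS1         50       50     0.691  0.0819    0.813 0.0562
```

Mean AUPR 0.69 against a 0.20 positive base rate: the ranking concentrates
true interactions near the top. `make_folds(..., "CVS2")` / `"CVS3"` score
the harder cold-start settings (whole novel-drug rows / novel-target columns
held out), `grid_search()` tunes `p, λ, μ₁, μ₂, ν₁, ν₂` on inner folds, and
`autoplot()` draws convergence curves, per-fold metric distributions and
AUPR surfaces.

A command-line front end wraps the same functions:

```sh
Rscript $(Rscript -e 'cat(system.file("cli/dtimc.R", package="dtimc"))') \
  cv --interactions admat.txt --drug-sim simmat_d.txt --target-sim simmat_t.txt \
  --settings CVS1,CVS2 --out-dir results/
```

Subcommands `simulate`, `fit`, `cv`, `grid`; every run writes a
`config.json` snapshot from which it can be reproduced exactly.

## Vignette

`vignettes/multi-graph-completion.Rmd` documents the model and its
assumptions, the similarity/Laplacian preprocessing, the degenerate-case and
tie-breaking conventions, what the synthetic generator does and does not
emulate, and known limitations.
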