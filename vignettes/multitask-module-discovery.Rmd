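---
title: "Multitask sparse factor regression for miRNA-mRNA module discovery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multitask sparse factor regression for miRNA-mRNA module discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtfr)
```

## The model

MicroRNAs repress their target mRNAs, and that repression is organized:
a small set of co-acting miRNAs tends to regulate a small set of
co-regulated mRNAs. When several cancer cohorts share a tissue of origin,
part of this regulatory structure is common to the tissue and part is
private to each cohort. `mtfr` models both at once.

For cohort $k$ with standardized miRNA matrix $X_k$ ($N_k \times D$) and
mRNA matrix $Y_k$ ($N_k \times T$), the model is a reduced-rank regression

$$Y_k = X_k \, [W_{XS}\; W_{Xk}] \begin{bmatrix} W_{YS} \\ W_{Yk}
\end{bmatrix} + E_k, \qquad E_k \sim \mathcal N(0, \sigma^2),$$

where the shared pair $W_{XS} \in \mathbb R^{D\times R_s}$,
$W_{YS} \in \mathbb R^{R_s \times T}$ is common to all cohorts and the
private pair $W_{Xk} \in \mathbb R^{D \times R_k}$,
$W_{Yk} \in \mathbb R^{R_k \times T}$ belongs to cohort $k$ alone. Each
rank-one component — one column of an X-side block with the matching row of
its Y-side block — is a *regulatory module*. Writing a module once in the
shared block costs one penalty; duplicating it into every cohort block
costs $K$ penalties, which is what pushes genuinely common structure into
the shared pair.

The fit minimizes

$$\tfrac12 \sum_k \big\lVert Y_k - X_k [W_{XS} W_{Xk}]
\left[\begin{smallmatrix} W_{YS} \\ W_{Yk} \end{smallmatrix}\right]
\big\rVert_F^2
+ \lambda_1 \lVert \cdot \rVert_{1} + \lambda_2 \lVert \cdot \rVert_F^2
\;\text{(X-side blocks)}
+ \lambda_3 \lVert \cdot \rVert_{1} + \lambda_4 \lVert \cdot \rVert_F^2
\;\text{(Y-side blocks)},$$

an elastic-net penalty on every block: the $\ell_1$ parts keep modules
sparse (interpretable member lists), the squared-Frobenius parts group
correlated features and keep the factorization well scaled.

### Assumptions

* Columns of $X_k$ and $Y_k$ are centered and scaled to unit standard
  deviation. All preprocessing ends with per-cohort standardization so this
  holds exactly on the data being fitted.
* Errors are iid Gaussian. Count overdispersion is only absorbed via the
  log2 transform.
* The regulatory map is approximately linear and low-rank in log space.

## Preprocessing

`preprocess_cohorts()` applies, in order: the expression filter (a feature
must be expressed — strictly positive — in at least half the samples;
features exactly at one half are kept), `log2(v + 1)` (the pseudocount of 1
maps zero counts to zero and is configurable), cross-cohort alignment
(samples intersected within a cohort, features intersected across cohorts),
and per-cohort column standardization. The filter runs on raw values
because presence/absence is only meaningful there; standardization runs
last because any later row or column restriction would break it.
Zero-variance columns cannot be scaled and are removed with a warning; a
removal in one cohort propagates to all so feature lists stay identical.
Standardization statistics are computed per cohort, not pooled: each
cohort enters the loss through its own $X_k, Y_k$, so each should satisfy
the scale assumption separately.

## Optimization

With ranks fixed, the problem is convex in all X-side blocks jointly (Y
fixed) and vice versa, but not jointly convex. `mtfr_fit_fixed_ranks()`
performs block-coordinate *prox-linear* rounds: for each block in turn —
Y-side first ($W_{YS}$, each $W_{Yk}$), then X-side ($W_{XS}$, each
$W_{Xk}$) — take a gradient step on the smooth part and apply
soft-thresholding,

$$W \leftarrow S_{\lambda/\mu}\!\left(W - \nabla h(W)/\mu\right),$$

with the step multiplier $\mu$ the exact Lipschitz constant of that
block's partial gradient. Because the smooth objective is quadratic in any
single block, these constants are available in closed form, e.g. for
$W_{XS}$: $\mu = \lVert\sum_k X_k^\top X_k\rVert_2 \,\lVert W_{YS}\rVert_2^2
+ 2\lambda_2$ (spectral norms). Each block update therefore majorizes the
objective and a full round can never increase it — the property the test
suite enforces to $10^{-10}(1+f)$. A multiplier floor of $10^{-8}$ guards
the cold start where a block and its ridge weight are both zero. The inner
loop stops when the relative objective change drops below
$\epsilon = 10^{-4}$ (default) or after `max_iter = 1000` rounds; hitting
the cap flags `converged = FALSE` and continues with a warning.

### Multi-start racing

The problem is non-convex, and its characteristic failure mode is an
*assignment* error: a cohort-private module parked in the shared block (or
vice versa) is a local optimum that block-coordinate descent cannot escape,
because moving a component between blocks requires passing through a
higher-objective state. Single random starts land in such optima often
enough to matter. `mtfr` therefore races `n_starts = 10` seeded random
starts for `burn_in = 200` rounds each and lets only the lowest-objective
one run to convergence. Empirically the best-objective start is also the
correctly assigned one: misassigned solutions pay for the cross-cohort
error a shared module imposes on the cohort it does not belong to. The
racing is fully seeded, so fits are reproducible bit for bit.

### Rank estimation

Ranks start at the upper bound `RU` for every block. After the inner loop
converges, each block pair is checked with `numeric_rank()` (singular
values above `rank_tolerance` relative to the largest; an all-zero block
has rank 0). Every pair whose rank falls short of its current
dimension is shrunk by one — all deficient blocks in the same restart —
and the problem is re-solved; a block may reach rank 0 and leave the model
entirely, which matters for degenerate data planted without structure in
some scope. Restarting includes the truncated previous solution (weakest
component of each reduced block dropped) as one candidate next to the
fresh random starts, so information is not thrown away but can be
overruled. Total rank strictly decreases each restart, so the loop
terminates; at termination every surviving block is full rank by
construction. The default `rank_tolerance = 0.15` measures *effective*
rank. Under the elastic net, a spurious component is shrunk hard but not
always to exact zero: it typically survives at 10--40% of the block's
top singular value while genuinely used components sit above 60%. A
machine-precision cutoff would declare such blocks full rank and stall
the reduction; the relative cutoff treats "numerically present but not
pulling its weight" as deficient, in the spirit of singular-value-ratio
estimators of factor number. Components of a *planted* module are
occasionally weak enough to be pruned too — that is the estimator's
bias toward parsimony, visible in the validation study's rare
under-estimates.

## Choosing the penalties

`cross_validate()` runs four-fold cross-validation over a grid of
$(\lambda_1,\lambda_2,\lambda_3,\lambda_4)$ combinations. Fold membership
is assigned once per cohort (seeded, balanced) and reused for every
combination, so combinations are compared on identical splits. Within a
fold, training-fold means and standard deviations standardize both the
training and the held-out data — the held-out fold never contributes to
the statistics it is scored under. The score is RMSE between predicted and
held-out mRNA values pooled over cohorts, averaged over folds; exact ties
break toward the smallest $(\lambda_1, \lambda_3, \lambda_2, \lambda_4)$
lexicographically, for determinism. Presets `cv_grid_preset("blood")`,
`"kidney"`, `"lung"` carry the cohort-size-scaled value sets used for the
TCGA-scale experiments; synthetic studies at the package's default
simulation scale use smaller values (the penalties scale with $N$ and
feature counts).

Prediction quality is reported as NRMSE: per-mRNA RMSE divided by that
mRNA's observed spread, averaged over mRNAs. The default normalization is
the observed standard deviation (computed with the same $1/N$ as the RMSE
numerator), which makes the per-column-mean predictor score exactly 1 —
values below 1 measure variance explained beyond the trivial predictor. A
range normalization is available by flag.

## From blocks to modules

`extract_modules()` rewrites each fitted block pair as
$\widetilde W_X D_X D_Y \widetilde W_Y$ with unit-norm columns/rows and the
removed norms on the diagonals. The product $D_X[r]\,D_Y[r]$ is module
$r$'s importance; modules are ranked by it within each scope. The
normalization acts on columns of $W_X$ and rows of $W_Y$ — the rank-one
components — which is the only orientation under which unit-norm module
vectors and $R \times R$ diagonals exist for a $D\times R$ by $R \times T$
factorization. Two gauge freedoms are fixed deterministically: scale moves
between the two diagonals without changing the product (harmless), and
each module's sign is chosen so the largest-magnitude miRNA weight is
positive, with the mRNA vector flipped jointly.

A feature belongs to a module when its unit-norm weight magnitude strictly
exceeds $2/\sqrt{\text{(number of features)}}$ — twice the
root-mean-square weight of a uniformly spread module. Strict inequality
means a weight exactly at the threshold is excluded.

## Downstream filters

**Survival.** For each module with at least one selected mRNA, patients of
the relevant cohort are split into two groups by 2-means clustering on the
(re-standardized) expression of the module's selected mRNAs — best of 20
seeded restarts; the group with lower mean expression is always labeled 0
so outputs are reproducible — and the groups are compared with the
log-rank test (`survival::survdiff`, $\chi^2_1$). A cohort module is
tested in its own cohort; a tissue module is tested in *every* cohort and
must reach $p < \alpha$ in all of them. No multiplicity correction is
applied by default (module screening convention); Benjamini-Hochberg is
available via `p_adjust`.

**Transcription factors.** `tf_permutation_test()` compares the TF content
of a module's selected mRNAs against draws of equally sized random gene
sets from the expressed-mRNA universe (default 10,000 draws). The
empirical p-value uses the add-one estimator
$(1 + \#\{\text{null} \ge \text{observed}\})/(n_{\text{perm}} + 1)$, which
can never return zero. With several modules, their observed TF percents
are compared to the pooled null with a one-sided Mann-Whitney test in the
enrichment direction. The null mean converges to the hypergeometric
expectation $|\text{TF} \cap \text{universe}|/|\text{universe}|$, which the
tests verify within Monte-Carlo error.

## The synthetic-data generator

`simulate_multitask()` generates data under the model's own generative
assumption: iid standard-normal miRNA profiles, planted sparse blocks
(each weight zero with probability `sparsity = 0.9`, otherwise Gaussian;
vectors are redrawn if all-zero so planted ranks are exact), responses as
the noiseless linear map plus iid Gaussian noise. The noise level is set
through a signal-to-noise ratio,
$\mathrm{SNR} = \lVert Y^0 \rVert_F / (\sigma\sqrt{\#\text{entries}})$,
default 2 — structure clearly present but far from noiseless. Ground truth
is kept pre-standardization and all recovery comparisons use cosine
similarity of directions, because standardization rescales coefficients
but preserves module directions.

The default study conditions — 2 cohorts, 60 miRNAs, 120 mRNAs, 150
samples per cohort, planted ranks $(R_s, R_1, R_2) = (2, 1, 1)$, sparsity
0.9, SNR 2, `RU = 4` — are the regime the validation suite measures:
penalty weights chosen once by cross-validation on an independent
realization, then ten seeded fits scored for exact rank recovery, matched
module cosine similarity, and selection recall.

What the generator does *not* emulate: negative-binomial count noise,
batch effects, confounders, correlated miRNA profiles, or realistic
feature dimensions (real cohorts have ~500 miRNAs and ~17,000 mRNAs).
Passing the recovery study shows the estimator recovers planted structure
under its own model at moderate noise — not that TCGA-scale data meet
those assumptions.

**A note on the recall metric.** Selection recall is measured against the
planted supports on *both* feature sides of each matched module (miRNA and
mRNA). The miRNA side alone is bounded away from 1 by construction: a
planted support entry of a unit-normalized Gaussian module vector exceeds
the selection threshold $2/\sqrt D$ with probability
$P(|z| > 2\sqrt{1-\text{sparsity}}) \approx 0.53$, independent of $D$ — a
perfectly estimated module still "misses" its weakest planted members,
exactly as the selection rule intends. Both-sides recall at the study
conditions runs near 0.7.

## Survival simulation

`simulate_survival()` draws exponential event times whose log-hazard is
proportional to the standardized module score (`effect` is the log-hazard
ratio per standard deviation; the default baseline hazard of 1/365 puts
median survival near one year at effect 0). Censoring times are
independent exponentials whose rate is solved by root finding so the
expected censored fraction matches `censoring_rate`; at 0 no one is
censored. These are the positive and negative controls for the survival
filter: effect 0 gives calibrated (uniform) log-rank p-values, effect 1.5
at $n = 200$ is detected with high power.

## Numerical choices, in one place

| Quantity | Default | Why |
|---|---|---|
| pseudocount | 1 | maps zero counts to zero in log2 |
| $\epsilon$ (stop) | $10^{-4}$ | relative objective change |
| `max_iter` | 1000 | per rank configuration |
| `init_scale` | 0.3 | Gaussian init sd; large enough to explore distinct basins |
| `n_starts` / `burn_in` | 10 / 200 | escapes assignment local optima |
| `rank_tolerance` | 0.15 | effective-rank cutoff under elastic-net shrinkage |
| multiplier floor | $10^{-8}$ | cold start with zero ridge |
| k-means restarts | 20 | 2-means local optima |
| `n_perm` | 10,000 | permutation null resolution |
| $\alpha$ | 0.05 | survival filter, uncorrected by default |

## Known limitations

* The objective is non-convex; multi-start racing makes good optima likely,
  not certain. Seeds are exposed everywhere so any run can be re-examined.
* Rank estimation relies on the $\ell_1$ penalty actually zeroing spare
  columns; with penalties chosen far below the cross-validated range, all
  blocks stay full rank at `RU` and the "estimated" ranks are just the
  bound.
* Shared/private separation is driven by the penalty economics described
  above; with a single cohort ($K = 1$) the shared and private blocks are
  not identifiable from each other, and the single-task reduction (shared
  block removed) is the meaningful configuration.
* The survival filter tests each module independently and, by default,
  without multiplicity correction; its output is a screen, not a
  confirmatory analysis.
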