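---
title: "Model and methods behind sgfa"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods behind sgfa}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sgfa)
```

## The generative model

`sgfa` models a collection of matrices `Y_gm` — one per sample group *g*
and feature view *m* — through a shared set of K latent factors:

$$Y_{gm} = Z_g W_m^\top + \epsilon_{gm}$$

Factors play the role of principal components generalized across
modalities: each factor ordinates samples along one axis centered at
zero, and its weights say which features move along that axis and in
which direction. The noise term is view-specific: Gaussian with a
per-feature, per-group precision $\tau_{dg}$ for continuous data, or a
Bernoulli / Poisson observation model for binary and count views.

All priors are conjugate (or made conjugate by local bounds), and each
unobserved variable carries one:

* **Weights**: spike-and-slab, $w_{dk} = s_{dk}\hat w_{dk}$ with
  $s_{dk}\sim\mathrm{Bern}(\theta_{km})$ and
  $\hat w_{dk}\sim N(0, \alpha_{km}^{-1})$. The Gamma-distributed ARD
  precision $\alpha_{km}$ is shared by a whole factor column within a
  view, so an irrelevant factor can be switched off *per view*; the
  Beta-distributed inclusion level $\theta_{km}$ sparsifies individual
  weights.
* **Factors**: the same two-level structure per *group* —
  $\alpha_{kg}$ shrinks factor columns group-wise (`ard_factors`,
  enabled by default), and an optional spike-and-slab
  (`spike_factors`, off by default) sparsifies individual factor
  values. With a single group and both switches off, the prior
  structure reduces to weight-side-only regularization, i.e. the
  classic sparse group-factor-analysis setting.
* **Noise**: $\tau_{dg}\sim\Gamma(a_\tau, b_\tau)$ for Gaussian views.

The factor-side ARD is the ingredient that makes multi-group designs
informative: variance that exists only in, say, one developmental stage
is absorbed by a factor whose precision explodes in the other stages,
which is exactly the differential-activity map reported by
`variance_explained()`.

### Prior hyperparameters

Defaults (all exposed in `sgfa_control()`):

| parameter | default | role |
|---|---|---|
| `alpha_a`, `alpha_b` | 1e-5 | Gamma prior on ARD precisions; broad and uninformative, prior mean 1 |
| `tau_a`, `tau_b` | 1e-5 | Gamma prior on noise precisions, likewise |
| `theta_a`, `theta_b` | 1 | uniform Beta prior on inclusion levels |

With shape and rate this small the posterior is dominated by the data
after a single sweep; the exact values only matter for pathologically
small blocks.

## Variational inference

The posterior is approximated by a mean-field factorization; each
spike-and-slab element keeps the *joint* factor
$q(s,\hat w) = q(s)\,q(\hat w\mid s)$, which avoids the well-known
pathology of factorizing $s$ and $\hat w$ independently (the point mass
and the slab would then fight each other). Every update is the exact
conditional optimum of the evidence lower bound (ELBO), so a full sweep
can never decrease it — the test suite fuzzes this property across
mixed-likelihood, partially observed data sets at a relative tolerance
of 1e-8.

One sweep updates, in this fixed order: local bound parameters
$\zeta$ → weights per view (factor columns in order, residuals kept
current) → factors per group → ARD precisions (weights, then factors) →
inclusion levels → noise precisions. Any order would preserve
monotonicity; fixing one makes runs reproducible.

Numerical choices worth knowing:

* **Initialization** is deterministic: factors start at the principal
  component scores of the feature-concatenated, group-stacked data,
  with missing entries contributing zero. The sign of each component is
  made canonical through its right singular vector (largest-magnitude
  loading positive), which makes fits invariant to sample order. A
  model-selection wrapper over random restarts is unnecessary under
  this scheme — rerunning the fit reproduces it bit for bit.
* **Missing data**: every sufficient statistic is restricted to
  observed positions. Values stored at masked positions are never read;
  the test suite replaces them with random junk and asserts bitwise
  identical fits.
* **Convergence** is declared when the ELBO changes by less than `tol`
  (default 1e-4) between sweeps. Because the absolute rule is
  scale-dependent (the ELBO grows with the number of observed entries),
  `convergence = "relative"` divides by the current ELBO magnitude; the
  validation suite uses the relative rule at 1e-6.
* **Factor death**: a factor whose posterior mean collapses below
  1e-10 everywhere is removed during training (`drop_inactive`). The
  user-facing filter is `prune_factors()` / `min_r2`, which applies the
  conventional 1 %-variance threshold after training and renumbers
  factors by total variance explained.

### Non-Gaussian views

Bernoulli data use the Jaakkola–Jordan quadratic bound on the logistic
log-likelihood with one auxiliary parameter $\zeta$ per observed entry;
its optimum is $\zeta^{*}=\sqrt{E[x^2]}$. Poisson counts use a softplus
rate $\lambda(x)=\log(1+e^x)$ and a quadratic lower bound obtained from
the uniform curvature bound $-f''(x) \le 1/4 + 0.17\,y$ of the
log-likelihood (the supremum of the y-coefficient is 0.16710, attained
near $x=0.5$; 0.17 is used as a safe constant). Both bounds are exact
at their expansion point and are verified to be dominated by the exact
log-likelihoods on a dense grid. Each bound is quadratic in the linear
predictor, so a non-Gaussian entry becomes a Gaussian pseudo-observation
with pseudo-precision $2\lambda(\zeta)$ (Bernoulli) or $1/4+0.17y$
(Poisson), and the Gaussian update machinery is reused unchanged. The
ELBO reported for such views is the bound surrogate.

The extra per-entry parameters make non-Gaussian training noticeably
slower; when a transformation to approximate Gaussianity exists (e.g.
M-values for methylation rates, log counts for expression), it is the
recommended route.

## Stochastic inference

For sample-rich data sets, `mode = "svi"` replaces full sweeps by
mini-batch updates. Batches are stratified per group (each batch holds
a proportional share of every group, within one sample), sampled
without replacement, and reshuffled every epoch from a seed-derived
stream. Local variables (factor rows, $\zeta$ entries of the batch) get
their exact update; global posteriors (weights, ARD, inclusion, noise)
move along a natural-parameter interpolation
$\eta \leftarrow (1-\rho)\eta + \rho\,\hat\eta$, where $\hat\eta$ is
the full-data optimum estimated from batch statistics scaled by
$N_g/|\text{batch}_g|$. This is the standard stochastic variational
inference construction, and it is the scheme for which the step-size
schedule

$$\rho(t) = \tau\,(1+\kappa t)^{-3/4}$$

(defaults $\tau = 1.0$, $\kappa = 0.25$, batch fraction 0.5) satisfies
the stochastic-approximation conditions. Two conventions had to be
fixed: the decay parameter $\kappa$ multiplies $t$ inside the base with
the exponent pinned at 3/4 (classical treatments sometimes use the
exponent itself as the forgetting rate), and $t$ counts *update steps*
(batches), not epochs. With a full batch and $\rho = 1$ a stochastic
step reproduces the deterministic sweep exactly — asserted to
near-machine precision in the tests. Convergence is always judged on
the full-data ELBO at epoch ends so that both modes use the same
stopping rule.

## Data processing

* Gaussian views are **centered per group** over observed entries
  before fitting (done by `sgfa()` unless `center = FALSE`), because
  the model is meant to explain within-group covariance, not group mean
  offsets. Bernoulli/Poisson views are never centered, which would
  break their support. Features with no observed value in a group are
  left untouched and flagged.
* **Highly variable feature selection** (`select_hvf()`) ranks features
  by their variance over observed entries pooled across groups *after*
  per-group centering, so group mean differences cannot dominate the
  ranking. Ties keep the earlier feature; retained features keep their
  original order.
* **Coverage counts to M-values** (`mvalue()`): the binomial MLE rate
  successes/trials is clamped to [0.001, 0.999] and mapped through
  $\log_2(r/(1-r))$. The clamp constant is this package's choice — it
  bounds M-values at roughly ±10, the scale real bisulfite data reach,
  while avoiding infinities at rate 0 or 1. Entries below the coverage
  filter (defaults follow the usual practice of at least 3 CpG, 10 CpH
  or 5 GpC measurements, settable via `min_trials`) become missing
  values, which the model handles natively.

## Variance decomposition and enrichment

`variance_explained()` reports, per factor and (group, view) block, the
coefficient of determination
$R^2 = 1 - \sum (y - \hat y)^2 / \sum y^2$ over observed entries of the
centered data, where the per-factor reconstruction uses only that
factor's rank-1 term and `total` uses all factors jointly. This is the
conventional reading of the statistic — the one for which a perfect fit
gives exactly 1. Per-factor values are not additive across factors
(factors need not be orthogonal); negative raw values (a factor that
fits worse than the zero model in some block) are clipped to 0 for
reporting, with raw values retained. For non-Gaussian views the
decomposition is computed on the Gaussian pseudo-data implied by the
final local bounds. All-zero observed blocks have undefined $R^2$ and
report `NA`.

`run_enrichment()` contrasts, per gene set, the foreground weights
against all remaining weights of the view with a **Welch** two-sample
t-test (the unequal-variance form is the safer default when a
parametric contrast is wanted), by default on absolute weights so that
bidirectional programs are detected; signed testing is available via
`use_absolute = FALSE`. P-values are Benjamini–Hochberg adjusted per
factor across sets and flagged at an FDR of 1 %. Under exchangeable
weights the flag rate is calibrated (verified at 1000 null replicates).

## The simulator

`sgfa_simulate()` draws data from the generative model itself:
factor values from scaled normals (per-(factor, group) activity
scales), weights from spike-and-slab draws (per-(factor, view) scales),
then Gaussian noise, Bernoulli-sigmoid or Poisson-softplus observation
sampling, and uniformly random masking. Group and view streams are
derived independently from the root seed, so resizing one view never
perturbs another's draws.

What it emulates: differential factor activity across groups and
views, sparse weights, mixed likelihoods, missing-completely-at-random
entries. What it does **not** emulate: count overdispersion beyond
Poisson, batch effects, doublets, or informative missingness. Passing
the validation suite therefore demonstrates correctness of the
inference machinery under the model's own assumptions, not robustness
to the ways real single-cell data violate them.

The validation suite runs at desk scale, chosen to finish in minutes on
one CPU while keeping estimates stable: 50 fuzzed data sets around
N≈20, D≈15 for monotonicity; N = 2000, D = 500, K = 5 for the
stochastic-vs-deterministic comparison; G = 3 × N = 100, M = 2 × D = 150
with noise variance 4 (per-factor signal-to-noise 0.25, a realistic
single-cell regime where shrinkage genuinely matters) for the designed
activity-pattern recovery, where the full model is also required to
beat a weight-only-ARD ablation; N = 200, D = 100 at SNR 5 for
single-factor recovery.

## Evaluation conventions

Recovered factors are matched to simulated ones greedily by maximal
absolute correlation of the factor values (one-to-one); unmatched true
factors count all their activity cells as errors. A factor is called
active in a group (view) when its $R^2$ reaches 1 % in any view
(group). Both conventions are this package's choices — factor models
identify factors only up to sign and order, so some matching rule is
required.

## Serialization

`write_sgfa()` stores one self-describing, versioned container (R
serialization format 3, platform independent, no timestamps — identical
inputs give identical bytes) holding dimensions and names, every
variational posterior, options, the training trace, the variance
decomposition and optionally the raw data. The loader refuses unknown
major versions and names missing components; containers saved without
data still answer weight/factor queries but refuse recomputation.

## Known limitations

* The model is linear; strongly non-linear manifolds are only coarsely
  captured. Exported factors (`factor_scores()`, `write_factors()`)
  are suitable inputs for non-linear embedding or pseudotime tools.
* Features are independent in the prior; regulatory structure between
  features is not used.
* The absolute convergence rule is scale dependent — prefer the
  relative rule for large data sets.
* Stochastic mode pays off only when samples clearly outnumber
  features; otherwise plain VI is faster.
* Negative-binomial / zero-inflated likelihoods are out of scope;
  transform to a Gaussian scale where possible.
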