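---
title: "Spatiotemporal disease mapping on disconnected graphs: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatiotemporal disease mapping on disconnected graphs: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stdismap)
```

## The problem

District-level health outcomes — the motivating case is under-five
mortality aggregated from household surveys — arrive as count panels: for
each areal unit $i = 1,\dots,S$ and survey period $t = 1,\dots,T$ we
observe an event count $O_{it}$ and an at-risk total $N_{it}$, plus
district-level covariate proportions. Two features make naive analysis
misleading. First, neighbouring districts and adjacent periods are
correlated, and the residual correlation changes over time (space–time
interaction). Second, when the study region spans several countries the
adjacency graph is *disconnected*: intrinsic spatial priors are rank
deficient per component, and each component needs its own identifiability
constraint (and, plausibly, its own variance).

`stdismap` implements the full hierarchical model for this setting with
approximate Bayesian inference, model-comparison criteria, variance
partitioning, and a ground-truth synthetic generator.

## Model

Counts are Poisson with internally standardized expected counts as offset,

$$O_{it} \mid \omega_{it} \sim \text{Poisson}(e_{it}\,\omega_{it}),
\qquad e_{it} = N_{it}\,\frac{\sum_{it} O_{it}}{\sum_{it} N_{it}},$$

so $\omega_{it}$ is the multiplicative departure of a cell from the pooled
rate, $\mathrm{SMR}_{it} = O_{it}/e_{it}$ its crude estimate, and
$\sum e = \sum O$ holds by construction. Cells with zero exposure are
dropped from the likelihood rather than imputed. The log relative risk is
additive:

$$\log \omega_{it} = \beta_0 + x_{it}^\top \beta + v_i + u_i + \gamma_t +
\phi_t + \psi_{it}.$$

In matrix form (time-major layout: the length-$TS$ predictor is $T$ blocks
of $S$ areas) the design maps are $\mathbf 1_{TS}$ for the intercept,
$X$ for the covariates, $\mathbf 1_T \otimes I_S$ for $v$ and $u$,
$I_T \otimes \mathbf 1_S$ for $\gamma$ and $\phi$, and $I_{TS}$ for
$\psi$; `assemble_eta()` and `design_maps()` expose them, and a loop-based
elementwise oracle in the tests confirms the equivalence. Covariates are
treated as spatio*temporal* ($x_{it}$, varying over both indices) and are
standardized to mean 0, sd 1 (population convention, divisor $n$), with
transform parameters retained, so each $\beta_k$ is a log relative-risk
change per one-sd covariate increase and $100(e^{\beta_k}-1)$ its percent
relative-risk change (`rr_percent_change()`).

### Priors

* $v \sim$ ICAR: structure $W_v = D - A$ (neighbour-count diagonal minus
  0/1 adjacency), the joint form whose full conditionals are Gaussian
  around the neighbour mean with variance inversely proportional to the
  neighbour count. Rank $S - C$ on a graph with $C$ components; null space
  = component indicators, giving one sum-to-zero constraint per component.
  Isolated areas have an all-zero row: their structured effect is fixed at
  0 by the constraint and the iid term absorbs their heterogeneity —
  standard island handling for intrinsic CAR on disconnected maps.
* $u_i \sim N(0, \sigma_u^2)$, $\phi_t \sim N(0, \sigma_\phi^2)$ —
  unstructured heterogeneity in space and time.
* $\gamma \sim$ RW1: structure $W_\gamma$ = second-difference-free
  first-order walk, rank $T-1$, overall sum-to-zero constraint.
* $\psi$: Knorr-Held interaction, the Kronecker taxonomy in time ⊗ space
  order — I: $I_T \otimes I_S$; II: $W_\gamma \otimes I_S$; III:
  $I_T \otimes W_v$; IV: $W_\gamma \otimes W_v$, rank $(T-1)(S-C)$. The
  null basis is assembled from Kronecker pairs of the factors'
  eigenvectors (a Kronecker eigenvalue vanishes iff either factor's does),
  so it is orthonormal by construction and its dimension
  $S + (T-1)C$ (type IV) counts the interaction constraints.

Structure matrices are **not** rescaled to unit generalized variance by
default — the variance parameters multiply the raw intrinsic structures —
but `st_model(scale_gmrf = TRUE)` provides the scaled variant (geometric
mean of the nonzero eigenvalues normalized to 1) for sensitivity analysis,
since scaled variances are more comparable across structures.

Component splitting: `split_intercept` / `split_covariates` estimate one
intercept / coefficient vector per component (indicator interactions; the
pooled fit is the default), and `split_spatial_variance` /
`split_interaction_variance` give each component its own ICAR (and type
III/IV interaction) variance, implemented as block-scaled structure
matrices. Whether interaction variances should split as well as spatial
ones is genuinely open; both are toggles.

### Hyperpriors

Each random-effect variance carries either

* `hyper_prior = "pc"` (default): a penalized-complexity prior,
  exponential on the standard deviation with $P(\text{sd} > 1) = 0.01$
  (configurable via `pc_u`, `pc_alpha`); or
* `hyper_prior = "gamma"`: the classical Gamma(1, 5e-4) prior on each
  precision.

The gamma default is widespread in applied INLA work and is retained as an
option, but it was deliberately **not** made the default here: on the log
precision $\theta$ its density $\propto \exp(\alpha\theta - b e^\theta)$
increases until $\tau = \alpha/b = 2000$, so in directions the likelihood
barely identifies — the BYM-type splits of spatial signal between $v$ and
$u$, or temporal signal between $\gamma$ and $\phi$ — the posterior mode
slides to the prior's own mode at variance $5\times10^{-4}$. That collapse
oversmooths the corresponding field, transfers its share of uncertainty
nowhere, and measurably degrades the frequentist calibration of the fixed
effects (the parameter-recovery test in the suite is exactly this
experiment). The PC prior's mass decays with the sd, removing the interior
mode at tiny variance while remaining weakly informative on the
log-relative-risk scale, where field sds above 1 (relative risks varying
by a factor $>e^2$ across districts) are substantively implausible. Fixed
effects get a vague Gaussian ridge (precision $10^{-4}$) so the joint
posterior is proper.

## Inference

The model is a latent Gaussian model; inference is a simplified INLA
scheme.

**Constraint handling.** Every intrinsic block is reparameterized onto an
orthonormal basis of its constraint null-space complement (eigenvectors
with nonzero eigenvalue; for the interactions, Kronecker pairs). The
reduced prior precision $Z^\top W Z$ is full rank, the reduced model is an
ordinary unconstrained latent Gaussian model, and every sum-to-zero
constraint holds *exactly* rather than to solver tolerance. This is the
projection form of conditioning by kriging; at this problem scale (latent
dimension a few hundred) dense eigendecompositions are cheap and the usual
sparse-Cholesky kriging corrections would add machinery without benefit.

**Gaussian approximation.** For fixed variances $\theta$,
Newton–Raphson on $\log p(z \mid y, \theta)$: latent start at 0 (or a warm
start from the previous $\theta$), second-order Poisson expansion at the
current predictor, step-halving if the objective decreases, convergence
when the largest step falls below $10^{-6}$, cap 50 iterations (an error
with the step trace is raised otherwise). The linear predictor is clamped
at 40 inside the exponential to keep intermediate iterates finite.

**Hyperparameter integration.** $\log p(\theta \mid y)$ is the Laplace
approximation
$\log p(y \mid z^*) - \tfrac12 z^{*\top} Q z^* + \tfrac12 \log|Q(\theta)|
- \tfrac12 \log|Q^*(\theta)| + \log p(\theta)$. The mode is found by BFGS
on the log precisions (numerical gradients; Nelder-Mead fallback),
curvature by central finite differences (step 0.15). With at most two
active variances a full grid (default 7 points/dimension over ±2.5 sd) is
integrated; with more, a CCD-style design (centre + axial points at ±1.2
sd) — the weights are the normalized Laplace values, i.e. point masses, an
approximation documented here rather than hidden. `hyper_grid = "eb"`
keeps the mode only (empirical Bayes), which the replicate-heavy tests use
for speed. Latent marginals are Gaussian mixtures over the design points;
fitted relative risks are reported as $\exp$ of the mixture mean with
lognormal-style intervals $\exp(\hat\eta \pm 1.96\,\text{sd})$.
Hyperparameter summaries moment-match the mixture on the log-precision
scale and are reported as **variances** (labelled as such, since intrinsic
"variance" parameters are conditional, not marginal, variances).

**MCMC oracle.** `mcmc_st()` samples the exact posterior of the same
reduced model: the latent field by an independence proposal from the
Gaussian approximation at the current $\theta$ (recomputed whenever a
hyperparameter move is accepted), each log precision by an adaptive
random walk (target ~44% acceptance, adaptation during burn-in).
High acceptance of the independence proposal indicates a good
approximation and is not warned about; sub-5% acceptance is. The oracle is
the package's validation route for the approximate fit — the test suite
compares fixed-effect posterior means on disconnected toys at tolerance
0.05 and a single-cell model against direct quadrature.

**Spatial confounding.** `st_model(orthogonalize = TRUE)` (default off)
adds constraints $X^\top A_b\,x_b = 0$ for the structured spatial and
interaction fields — restricted spatial regression. With the flag on, the
fitted fields are exactly orthogonal to the covariate span and the
coefficients move toward the covariate-only GLM estimates; with it off,
smoothing priors may absorb covariate-aligned variation. The mechanism by
which published analyses "address" spatial confounding is usually left
unstated; making it an explicit, optional constraint keeps both fits
available for comparison.

## Model comparison and variance partitioning

`dic()` uses the textbook decomposition $\bar D = E[-2\log L]$,
$p_D = \bar D - D(\text{posterior mean})$, $\text{DIC} = \bar D + p_D$,
with the unsaturated Poisson deviance (constants cancel in comparisons).
`waic()` uses pointwise log predictive densities over posterior draws:
$\text{lppd} = \sum_c \log \overline{\exp(\ell_c)}$,
$p_{\text{WAIC}} = \sum_c \widehat{\text{var}}(\ell_c)$,
$\text{WAIC} = -2(\text{lppd} - p_{\text{WAIC}})$. `compare_st()` checks
the fits share identical data and flags DIC differences above 3 — the
conventional meaningful-difference rule — relative to the best model.

`variance_partition()` maps each family's posterior-mean effect vector
onto the area-period grid and takes empirical variances, normalized to
proportions. Hyperparameter values are deliberately *not* used: intrinsic
prior variances are conditional quantities and would misstate each
family's realized share. The temporal share pools the RW1 trend and the
iid temporal effect.

## The synthetic generator

`simulate_panel()` emulates the study design the package targets:

* geography — disjoint rook-contiguity grid lattices
  (`lattice_graph()`, default sizes 11+10+9+7 = 37 areas in 4 components,
  mirroring a four-country, 37-district map);
* panel — default $T = 4$ survey periods; at-risk totals uniform on
  500–8000 per cell, echoing district survey denominators; a pooled event
  rate of 0.09, a typical under-five mortality proportion;
* covariates — logistic-scale Gaussian processes with component-level mean
  shifts and AR(1) ($\rho = 0.7$) temporal autocorrelation, then
  standardized; this deliberately *confounds* covariates with the spatial
  structure, the regime the model is meant to survive;
* effects — drawn from their exact constrained priors via spectral
  sampling (`sample_gmrf()`), so generated truth satisfies every
  constraint to machine precision;
* default true variances $(v, u, \gamma, \phi, \psi) =
  (0.30, 0.05, 0.36, 0.02, 0.10)$ — chosen once as a realistic
  disease-mapping calibration on the log-relative-risk scale: spatial sds
  near 0.55, a temporal trend strong enough to move relative risks by a
  factor ~2 across periods (the magnitude of secular mortality decline in
  multi-country survey series), heterogeneity and interaction smaller;
  temporal variability dominant among the main effects, as such series
  show;
* expected counts by the same internal standardization the analysis uses,
  via a two-pass scheme: a provisional Poisson draw at the configured
  pooled rate fixes the standardization rate, final counts are drawn from
  $e\,e^{\eta}$ — generator and analysis thus share one definition of $e$.

The generator does **not** emulate two-stage cluster sampling, sampling
weights, GPS displacement, or boundary changes between survey rounds.
Passing tests therefore demonstrate correctness of the model and inference
under the stated generative assumptions, not robustness to survey-design
artefacts.

## Numerical choices and degenerate inputs

* Rank/null decisions use relative eigenvalue tolerances ($10^{-9}$ of the
  largest); constraint residual checks in the suite assert $10^{-8}$ or
  better, and in practice residuals sit at machine precision because
  constraints are eliminated, not penalized.
* Log precisions start at 0 (variance 1); latent fields start at 0;
  Newton uses step-halving; Cholesky failures retry once with a
  $10^{-8}$-scaled jitter.
* Zero-exposure cells: $e = 0$, excluded from the likelihood; SMR reported
  `NA` (with a warning if deaths are positive). Constant covariate columns
  are an error naming the column. Graphs with a single area, empty edge
  sets, and isolated areas are all legal.
* Determinism: fits are deterministic given inputs; all sampling
  (generator, posterior draws, MCMC) runs under explicit seeds through an
  RNG-state-preserving wrapper, so the same seed reproduces results
  bit for bit without disturbing the caller's RNG.

## Problem sizes used by the test suite

The suite exercises the full study scale (37 areas × 4 periods) for fits
and constraint checks; replicate experiments use 36 areas in 4 components
(40 replicates for interval coverage), 16 areas for the ΔDIC and
variance-partition rate experiments, and a 5-area disconnected toy (path
plus isolate) for the MCMC-oracle comparisons, with 12–15k oracle
iterations. These sizes were chosen so the entire suite runs in a few
minutes while leaving each experiment enough replicates for its rate
thresholds to be meaningful.

## Known limitations

* The hyperposterior is explored by a grid/CCD with point-mass weights;
  very skewed hyperposteriors are summarized only through their
  moment-matched lognormal intervals.
* Latent marginals are simplified Gaussians (mixed over the
  hyperparameter design), not per-element nested Laplace corrections; the
  MCMC-oracle tests bound the resulting error for the configurations
  exercised.
* Dense algebra caps practical problem sizes around a few thousand cells;
  the intended scale (tens of districts, a handful of periods) is far
  below that.
* Contiguity is shared-border only; distance/centroid neighbourhoods,
  RW2/seasonal temporal priors, and Leroux/BYM2 reparameterizations are
  out of scope.
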