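---
title: "Stage-structured state-space models with survey bias parameters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stage-structured state-space models with survey bias parameters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`stagebias` fits a state-space model for a population whose cohorts pass
through `n` sequential life stages. Cohorts do not overlap: stage-`n`
individuals reproduce and die, so the dynamics restart from the adults of
the previous cohort. Writing `N[i,t]` for the abundance of stage `i` in
cohort `t`, the process model is

* recruitment: `N[1,t] = rho[t] * N[n,t-1]`, with
  `log(rho[t]) ~ Normal(w_R[t,] %*% beta_R, sigma_pR^2)`;
* survival: `N[i,t] = phi[i-1,t] * N[i-1,t]` for `1 < i <= n`, with
  `logit(phi[i,t]) ~ Normal(w_Si[t,] %*% beta_Si, sigma_pSi^2)`.

Each design matrix has an intercept column followed by environmental
covariates, so the vital rates are log-linear (recruitment) or
logit-linear (survival) in the covariates, with genuine biological
year-to-year stochasticity expressed by the process SDs `sigma_p`.

Each stage is observed by an abundance-index survey whose expected value is
proportional to, but not equal to, the true abundance:

```
Y[i,t] ~ Log-Normal(log(psi[i] * N[i,t]) - sigma_o[i,t]^2 / 2, sigma_o[i,t]^2)
```

`psi[i]` is the survey's multiplicative observation bias (the analogue of a
catchability coefficient) and `sigma_o[i,t]` the known log-scale sampling SD
of the index. The `-sigma^2/2` shift makes the index unbiased for
`psi * N` on the natural scale, which is how index time series are usually
constructed. An optional index of the initial adult abundance `N[n,0]`
enters with the stage-`n` survey's bias. Two stages may share a survey
label, in which case they share one `psi`.

### Identifiability

Conditional on the latent vital rates, every abundance is `N[n,0]` times a
product of vital rates, so the likelihood involves `N[n,0]` and the biases
only through the products `N[n,0] * psi[i]`: multiplying the initial
abundance by `c` while dividing every bias by `c` changes nothing
(`rescale_params()`; the invariance is exercised to `1e-10` relative error
in the test suite). Fitting therefore requires an anchor: at least one
bias parameter, or the initial abundance, must be fixed
(`fit_mle(..., fix_psi = c(S4 = 1))`). If the anchor is fixed at a *wrong*
value the state-process estimates are unaffected; the abundance scale and
the free biases converge to rescaled targets,
`N[n,0] * psi_j / psi_ref` and `psi_i * psi_ref / psi_j`
(`adjusted_true_values()`), and ratios of estimated biases still track
ratios of the true ones. Even when formally identified, the model is
*practically* near-redundant: the bias parameters and the vital-rate
intercepts are strongly confounded, which is visible as ridges in profile
likelihoods and elongated joint posteriors. The package's diagnostics
(`profile()`, `intercept_grid_scan()`, `joint_posterior_summary()`) are
built to expose exactly this.

## Parameters that matter

| parameter | meaning | scale / units | default source |
|---|---|---|---|
| `beta_R`, `beta_S*` | vital-rate regression coefficients | log / logit scale per SD of covariate | estimated |
| `sigma_p_R`, `sigma_p_S*` | process SDs | log / logit scale | estimated; simulator presets 0.50 (low information) or 0.25 (high) |
| `sigma_o` | observation SD of each index | log scale, treated as known | simulator presets 0.10 / 0.05 |
| `psi` | survey bias | dimensionless multiplier | simulator presets (0.20, 0.10, 0.40, 0.50), or 1 when unbiased |
| `log_N_init` | initial adult log-abundance | log individuals | preset 13.82 |

The "low information" and "high information" simulator presets differ in
the steepness of the covariate effects (slopes 1.30 vs 2.00 on survival,
-0.50 vs -1.00 on recruitment) and in both noise levels; they bracket the
range where bias parameters are practically estimable.

## What the simulator emulates, and what it does not

`simulate_scenario()` generates data with the structure of a four-stage,
twenty-cohort monitoring program: one survey per stage, one standard-normal
covariate per vital rate, constant known observation SDs and an observed
initial adult index. This mirrors the skeleton of real multi-survey
monitoring data while remaining fully synthetic. Real datasets differ in
ways the simulator deliberately ignores: covariates are serially
correlated and cross-correlated, observation SDs vary between years,
surveys start and stop (the readers accept such gaps; the simulator never
generates them), and survey biases may drift over time. Passing tests
therefore demonstrate the correctness of the machinery and the qualitative
inferential phenomena (bias of ignored `psi`, confounding of estimated
`psi`), not that any particular real dataset is this well behaved.
Covariates are drawn independently for each vital rate; whether shared or
distinct covariates are used barely matters for the phenomena studied, and
distinct draws avoid accidental collinearity between rates.

## Inference

### Maximum likelihood

The latent vital rates are integrated out by the Laplace approximation.
The production path (`fit_mle()`) uses TMB's automatic differentiation of
the same joint density that the package also implements in interpreted R;
the two implementations agree to near machine precision and are
cross-checked in the tests. Free parameters are optimized on unconstrained
scales (`log sigma`, `log psi`, `log N`, raw coefficients) to avoid
boundary failures. Convergence of the outer optimizer and positive
definiteness of its Hessian are reported *separately* (`converged`,
`hessian_pd`), because near-redundant fits routinely converge to a point
where the Hessian is numerically singular; the replicate studies resolve
such replicates by simulating a fresh dataset (up to ten attempts per
slot, counted and reported).

The pure-R Laplace path (`inner_mode()`, `marginal_nll()`) runs a Newton
optimizer with analytic gradients and Hessians of the latent block
(tolerance `1e-8` on the gradient max-norm, backtracking line search,
ridge fallback for indefinite Hessians). It backs the one-step-ahead
residuals and is validated three ways: against finite differences, against
a closed-form linear-Gaussian marginal in a log-normal-survival variant of
the model (where Laplace is exact), and against adaptive quadrature on a
one-cohort model (agreement well within 1%).

One-step-ahead residuals use the Gaussian (Laplace) filtering
approximation: each observation is standardized against the predictive
distribution of its log-index given all earlier observations, with the
predictive variance combining the known observation variance and the
propagated latent uncertainty. This is adequate because the observation
noise is log-normal, making the conditional nearly Gaussian; particle
methods would add cost without changing the diagnostic story.

Model comparison uses AICc with the effective sample size taken as the
number of non-missing index observations, including the initial adult
index; no other defensible count presents itself for this data layout.
Profile likelihoods re-optimize all remaining parameters at each grid
point, warm-started outward from the MLE; the conventional chi-square
1-df 1.92-drop rule is exposed as the default interval cutoff.

### Bayesian sampling

`sample_posterior()` implements an adaptive Metropolis-within-Gibbs
sampler over the parameters (on their natural scales) and the latent
rates (one block per cohort), with several specialized moves designed for
this model's geometry:

* exact conjugate Gibbs draws of the regression coefficients given the
  latent rates, and of the initial log-abundance (Gaussian truncated to
  its uniform prior);
* non-centered "sweep" translations of a coefficient together with its
  latent row, which cross the coefficient-latent funnel;
* "orbit" slice moves that rescale a bias parameter jointly with the
  exactly compensating latent rates and the design-projected coefficient
  shift. Along such an orbit every point fits the observations equally
  well, so the move walks the bias-intercept confounding ridge directly;
  the family is a one-parameter flow, making slice sampling along it a
  valid group move with the appropriate Jacobian;
* correlated "grand" jumps of the whole parameter block with latent states
  carried in non-centered form, using a proposal covariance taken from a
  Laplace fit and re-estimated from the chain's own burn-in history.

Proposal scales adapt in batches of 50 iterations toward standard
acceptance targets during burn-in only, and the observation likelihood is
annealed in over the first half of burn-in so that overdispersed starting
points cannot strand a chain in a low-probability arm of the ridge. After
burn-in the kernel is fixed. The sampler is validated by prior recovery
with the likelihood switched off, by an exactly conjugate one-cohort
subproblem with a closed-form posterior, and by agreement of posterior
means with the MLE on well-identified data. Chains are bitwise
reproducible given a seed.

The default run of 4 chains by 20,000 iterations (first half discarded) is
a deliberate desk-scale choice; the confounding ridges of this model carry
long autocorrelation, and convergence diagnostics at this budget are
expected to sit near the conventional 1.1 split-R-hat warning level rather
than comfortably below it. Production analyses should use considerably
longer chains, exactly as one would with a general-purpose Gibbs engine.

## Numerical choices and degenerate inputs

* Latent states live on the log (recruitment) and logit (survival) scales,
  and the process densities are plain normals there with no Jacobian
  terms; this is the standard random-effects formulation for Laplace
  approximation and makes the latent block nearly Gaussian.
* Missing observations contribute exactly zero to every likelihood; the
  missingness mask also fixes the dependence pattern used by the analytic
  latent derivatives, which is computed once per dataset.
* `sigma_o` must be positive wherever an index is observed; indices must
  be positive; rescaling constants must be positive. Violations raise
  errors rather than silently propagating.
* Grid orderings in profiles and scans proceed outward from the MLE with
  warm starts from the nearest solved point; ties resolve toward
  increasing parameter values.
* Relative bias in the replicate studies is `(est - true) / |true|`, so
  that negative true coefficients keep the sign convention interpretable;
  for the rescaled (always positive) bias and abundance targets the two
  conventions coincide.

## Problem sizes used by the shipped tests

The test suite reproduces the study's qualitative conclusions at desk
scale: replicate studies use 200 replicates of the low-information
four-stage, twenty-cohort scenario per data-model pairing (the full-scale
version with 1000 replicates is available by changing one argument);
posterior sampling examples use 4 chains; oracle comparisons use one- to
five-cohort instances where exact answers are computable. These sizes were
chosen so that the whole suite completes in tens of minutes on a single
core while leaving every qualitative conclusion intact.

## Known limitations

* Bias parameters are constant per survey; covariate- or time-dependent
  catchability is out of scope.
* Cohorts must not overlap; iteroparous life histories need a different
  process model.
* The observation SDs are treated as known. Estimating them alongside the
  process SDs is a classic source of non-identifiability in state-space
  models and is deliberately excluded.
* The Laplace approximation is very accurate here but not exact; the
  Bayesian machinery provides the exact-likelihood counterpart, at the
  price of the mixing behaviour discussed above.
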