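# stagebias

Population monitoring programs often index each life stage of a species
with a different survey, and each survey sees only some fraction of the
animals that are really there. `stagebias` fits sequential life-stage
state-space models in which every abundance index carries its own unknown
multiplicative observation bias (a catchability-like constant), so that
several biased surveys can be combined into one coherent analysis of
recruitment and survival. The package is aimed at quantitative ecologists
and stock-assessment analysts who want to know what ignoring — or
estimating — such biases does to their vital-rate inference.

## The model

A cohort passes through `n` stages; stage-`n` adults reproduce and die.
With `N[i,t]` the abundance of stage `i` in cohort `t`:

```
N[1,t] = rho[t] * N[n,t-1]            log rho[t]     ~ N(w_R[t,] beta_R,  sigma_pR^2)
N[i,t] = phi[i-1,t] * N[i-1,t]        logit phi[i,t] ~ N(w_Si[t,] beta_Si, sigma_pSi^2)
Y[i,t] ~ LogNormal(log(psi_i N[i,t]) - sigma_o[i,t]^2/2,  sigma_o[i,t]^2)
```

`psi_i` is the bias of stage `i`'s survey and `sigma_o` is the known
log-scale sampling SD of the index. Because the likelihood depends on the
initial abundance and the biases only through the products `N[n,0] psi_i`,
one bias (or the initial abundance) must be fixed before fitting; fixing
it at a wrong value rescales the abundance estimates in a known way while
leaving the vital-rate inference untouched.

The package provides a fully seeded simulator with "low" and "high"
information presets, maximum-likelihood fitting by Laplace approximation
over the latent vital rates (with profile likelihoods, AICc,
likelihood-ratio tests and one-step-ahead residuals), an adaptive
Metropolis-within-Gibbs sampler with Gelman-Rubin diagnostics, and the
simulation experiments that quantify the consequences of ignoring or
misspecifying bias.

## Worked example

Simulate a high-information, biased, four-stage dataset and fit the model
that anchors identifiability by fixing the fourth survey's bias at 1
(its true value is 0.5 — deliberately wrong):

```r
library(stagebias)
sc  <- simulate_scenario(scenario_spec("high", biased = TRUE, seed = 1))
fit <- fit_mle(sc$data, fix_psi = c(S4 = 1))
fit
```

```
Life-cycle SSM fit (Laplace ML)
  log-likelihood 51.8666 | 16 free parameters | 81 observations
  converged: TRUE | Hessian positive definite: TRUE
        parameter estimate      se
1      log_N_init  13.1502 0.04865
2        beta_R_0   1.7068 0.07347
3        beta_R_1  -1.0900 0.05139
4       beta_S1_0   0.9485 0.25713
5       beta_S1_1   1.9563 0.15062
6       beta_S2_0   1.1262 0.17762
7       beta_S2_1   2.1255 0.12999
8       beta_S3_0   0.9418 0.17881
9       beta_S3_1   1.9002 0.19100
10  log_sigma_p_R  -1.6556 0.17369
11 log_sigma_p_S1  -1.0872 0.25328
12 log_sigma_p_S2  -1.5446 0.24483
13 log_sigma_p_S3  -1.7412 0.38226
14     log_psi_S1  -0.9231 0.06189
15     log_psi_S2  -1.5966 0.05074
16     log_psi_S3  -0.2041 0.03524
```

The regression coefficients land on the generating values
(`beta_R = (1.75, -1.00)`, survival pairs `(1, 2)`). Because the reference
bias was fixed at twice its true value, the estimates of the remaining
quantities converge to the *rescaled* truths: `exp(-0.9231) = 0.40`,
`exp(-1.5966) = 0.20` and `exp(-0.2041) = 0.82` are the doubled true
biases `(0.20, 0.10, 0.40)`, and `13.15` is `13.82 + log(0.5)`, the halved
initial abundance — exactly what the rescaling theory predicts:

```r
adjusted_true_values(sc$params, "S4", psi_ref = 1)
#> $log_N_init  13.12685
#> $psi         S1 0.4   S2 0.2   S3 0.8
```

Everything downstream works from the fit object: `profile(fit,
"log_psi_S3", grid)`, `osa_residuals(fit)`, `aicc(fit)`,
`vital_rate_curves(fit)`, `intercept_grid_scan(fit, ...)`, and the
Bayesian counterpart `sample_posterior(sc$data, fix_psi = c(S4 = 1))`.

The misspecification experiments are one call each:

```r
run_bias_study(200, scenario_spec("low", biased = TRUE), model = "fix_all")
```

simulates 200 datasets with biased observations, fits the model that
wrongly assumes no bias, and reports per-parameter relative bias, MSE and
sampling SDs (process SDs come out biased high, slopes distorted — the
cost of ignoring bias).

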