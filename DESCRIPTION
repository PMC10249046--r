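Package: stagebias
Title: Stage-Structured State-Space Population Models with Survey Bias
    Parameters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Fits sequential life-stage state-space models of population
    dynamics in which each life stage is observed by an abundance index
    carrying an unknown multiplicative observation bias (catchability).
    Provides the process model (log-normal recruitment, logit-normal
    survival with covariate-dependent means), the log-normal observation
    model with survey-specific bias parameters, a fully seeded simulator,
    maximum-likelihood inference by Laplace approximation over the latent
    vital rates (with profile likelihoods, AICc, likelihood-ratio tests and
    one-step-ahead residuals), Bayesian fitting by an adaptive
    Metropolis-within-Gibbs sampler with Gelman-Rubin diagnostics, and
    simulation experiments quantifying the consequences of ignoring or
    misspecifying observation bias.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE, load = "source")
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    TMB,
    MASS,
    jsonlite
LinkingTo:
    TMB,
    RcppEigen
Suggests:
    testthat (>= 3.0.0),
    numDeriv,
    mvtnorm,
    coda,
    withr
Config/testthat/edition: 3
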