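#' Simulation scenario specification
#'
#' A scenario maps deterministically to a preset parameter vector (see
#' [preset_params()]) plus the matching known observation-error SD. The two
#' information levels differ in how strongly the covariates drive the vital
#' rates and in how noisy process and observation are: the high-information
#' preset has steeper slopes, halved process SDs and halved observation SDs.
#'
#' @param info_level `"low"` or `"high"` data information content.
#' @param biased If `TRUE`, surveys carry the preset multiplicative biases
#'   `psi = (0.20, 0.10, 0.40, 0.50)`; if `FALSE` all `psi = 1`.
#' @param n_stages Number of life stages (the presets are defined for 4).
#' @param T Number of cohorts (default 20).
#' @param seed Integer seed for the simulator.
#' @return An object of class `"scenario_spec"`.
#' @export
scenario_spec <- function(info_level = c("low", "high"), biased = TRUE,
                          n_stages = 4L, T = 20L, seed = 1L) {
  info_level <- match.arg(info_level)
  structure(list(info_level = info_level, biased = isTRUE(biased),
                 n_stages = as.integer(n_stages), T = as.integer(T),
                 seed = as.integer(seed)),
            class = "scenario_spec")
}

#' Preset parameter vectors for the simulation scenarios
#'
#' Returns the four-stage parameter preset for the requested information
#' level. Low information: `beta_R = (1.00, -0.50)`, every survival
#' coefficient pair `(1.00, 1.30)`, all process SDs 0.50, observation SD
#' 0.10. High information: `beta_R = (1.75, -1.00)`, survival pairs
#' `(1.00, 2.00)`, process SDs 0.25, observation SD 0.05. Both share
#' `log N[4,0] = 13.82`. Biased scenarios use
#' `psi = (0.20, 0.10, 0.40, 0.50)`; unbiased ones `psi = 1` throughout.
#'
#' @param spec A [scenario_spec()].
#' @return A [lifecycle_params()] with attribute `"sigma_o"` (the scalar
#'   log-scale observation SD of the scenario).
#' @export
preset_params <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  if (spec$n_stages != 4L)
    stop("parameter presets are defined for the four-stage life cycle")
  low <- spec$info_level == "low"
  beta_R <- if (low) c(1.00, -0.50) else c(1.75, -1.00)
  beta_S1 <- if (low) c(1.00, 1.30) else c(1.00, 2.00)
  sigma_p <- if (low) 0.50 else 0.25
  sigma_o <- if (low) 0.10 else 0.05
  psi <- if (spec$biased) c(0.20, 0.10, 0.40, 0.50) else rep(1, 4)
  params <- lifecycle_params(
    n_stages = 4L,
    log_N_init = 13.82,
    beta_R = beta_R,
    beta_S = list(beta_S1, beta_S1, beta_S1),
    sigma_p_R = sigma_p,
    sigma_p_S = rep(sigma_p, 3),
    psi = psi
  )
  attr(params, "sigma_o") <- sigma_o
  params
}

#' Simulate vital-rate covariates
#'
#' One standard-normal covariate per vital rate, i.i.d. across cohorts, with
#' an intercept column of ones prepended. Reproducible given `seed`.
#'
#' @param T Number of cohorts.
#' @param n_stages Number of life stages.
#' @param m Covariates per vital rate: scalar or vector of length `n_stages`
#'   (recruitment first, then each survival transition).
#' @param seed Optional integer seed.
#' @return A [covariate_set()].
#' @export
simulate_covariates <- function(T, n_stages = 4L, m = 1L, seed = NULL) {
  if (T < 1L) stop("T must be >= 1")
  m <- rep(as.integer(m), length.out = n_stages)
  with_seed(seed, {
    draw <- function(k) cbind(1, matrix(stats::rnorm(T * k), T, k))
    covariate_set(w_R = draw(m[1]),
                  w_S = lapply(m[-1], draw))
  })
}

#' Simulate a dataset from the life-cycle state-space model
#'
#' Draws the latent vital rates from the process model, builds the abundance
#' series by the life-cycle recursion, and draws the observed indices from
#' the log-normal observation model with the survey biases in `params`.
#' The true latent states are returned alongside the data so that recovery
#' can be checked.
#'
#' @param params A [lifecycle_params()].
#' @param cov A [covariate_set()].
#' @param sigma_o Known log-scale observation SD: scalar, per-stage vector,
#'   or full `n x T` matrix.
#' @param seed Optional integer seed.
#' @param survey_of_stage Stage-to-survey map (defaults to `names(params$psi)`
#'   taken stage by stage).
#' @param include_Y_init If `TRUE` (default) also observe the initial adult
#'   abundance with the stage-`n` survey.
#' @return A list with elements `data` (an [ssm_dataset()]) and `latent`
#'   (the true [latent_states()]).
#' @export
simulate_dataset <- function(params, cov, sigma_o, seed = NULL,
                             survey_of_stage = NULL,
                             include_Y_init = TRUE) {
  n <- params$n_stages
  T <- cov$T
  sigma_o <- matrix(sigma_o, n, T)
  survey_of_stage <- survey_of_stage %||%
    names(params$psi)[pmin(seq_len(n), length(params$psi))]
  with_seed(seed, {
    log_rho <- stats::rnorm(T, drop(cov$w_R %*% params$beta_R),
                            params$sigma_p_R)
    logit_phi <- matrix(0, n - 1L, T)
    for (i in seq_len(n - 1L))
      logit_phi[i, ] <- stats::rnorm(T, drop(cov$w_S[[i]] %*% params$beta_S[[i]]),
                                     params$sigma_p_S[i])
    latent <- latent_states(log_rho, logit_phi)
    N <- build_abundances(params$log_N_init, latent, n, T)
    psi_stage <- params$psi[survey_of_stage]
    mu <- log(psi_stage) + log(N) - sigma_o^2 / 2   # psi recycled by row
    Y <- matrix(exp(stats::rnorm(n * T, mu, sigma_o)), n, T)
    Y_init <- NA_real_
    sigma_o_init <- NA_real_
    if (include_Y_init) {
      sigma_o_init <- sigma_o[n, 1]
      mu0 <- log(psi_stage[n]) + params$log_N_init - sigma_o_init^2 / 2
      Y_init <- exp(stats::rnorm(1, mu0, sigma_o_init))
    }
    list(data = ssm_dataset(Y, sigma_o, cov, survey_of_stage,
                            Y_init, sigma_o_init),
         latent = latent)
  })
}

#' Simulate a full scenario
#'
#' Convenience wrapper: preset parameters, fresh covariates and one simulated
#' dataset, all derived from the scenario's seed.
#'
#' @param spec A [scenario_spec()].
#' @return A list with `params`, `cov`, `data`, `latent` and `sigma_o`.
#' @export
simulate_scenario <- function(spec) {
  params <- preset_params(spec)
  sigma_o <- attr(params, "sigma_o")
  seeds <- child_seeds(spec$seed, 2L)
  cov <- simulate_covariates(spec$T, spec$n_stages, 1L, seed = seeds[1])
  sim <- simulate_dataset(params, cov, sigma_o, seed = seeds[2])
  list(params = params, cov = cov, data = sim$data, latent = sim$latent,
       sigma_o = sigma_o)
}
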