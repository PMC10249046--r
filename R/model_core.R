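#' Abundances implied by the latent vital rates
#'
#' Runs the deterministic life-cycle recursion: the first stage of cohort `t`
#' is recruited from last cohort's adults, `N[1,t] = rho[t] * N[n,t-1]`, and
#' each later stage survives from the one before, `N[i,t] = phi[i-1,t] *
#' N[i-1,t]`. Cohorts do not overlap: stage-`n` individuals reproduce and die.
#'
#' @param log_N_init Log of the initial adult abundance `N[n,0]`.
#' @param latent A [latent_states()] object (log/logit scale).
#' @param n Number of stages; must match `nrow(latent$logit_phi) + 1`.
#' @param T Number of cohorts; must match `length(latent$log_rho)`.
#' @return An `n x T` matrix of abundances with attribute `"N_init"` holding
#'   `N[n,0] = exp(log_N_init)`.
#' @export
build_abundances <- function(log_N_init, latent, n, T) {
  if (length(latent$log_rho) != T || nrow(latent$logit_phi) != n - 1L ||
      ncol(latent$logit_phi) != T)
    stop("latent state dimensions do not match n and T")
  logN <- log_abundances(log_N_init, latent$log_rho, latent$logit_phi)
  N <- exp(logN)
  attr(N, "N_init") <- exp(log_N_init)
  N
}

# log N[i,t] via cumulative sums: each abundance is N[n,0] times the product
# of every vital rate on the path to it (all rates of earlier cohorts, plus
# this cohort's recruitment and the survivals up to stage i - 1).
# log_phi_fun maps the stored latent survival scale to log(phi); the default
# is the logit scale of the production model.
log_abundances <- function(log_N_init, log_rho, logit_phi,
                           log_phi_fun = log_invlogit) {
  T <- length(log_rho)
  n <- nrow(logit_phi) + 1L
  log_phi <- log_phi_fun(logit_phi)
  # within-cohort cumulative survival: rows i = 1..n give log(N[i,t]/N[1,t])
  within <- rbind(0, matrix(apply(log_phi, 2, cumsum), nrow = n - 1L))
  # log N[n,t] - log N[n,t-1] = log rho_t + sum_j log phi_{j,t}
  adult_steps <- log_rho + colSums(log_phi)
  log_adult_prev <- log_N_init + c(0, cumsum(adult_steps))[seq_len(T)]
  log_first <- log_rho + log_adult_prev
  sweep(within, 2, log_first, "+")
}

log_invlogit <- function(x) -log1p(exp(-x))
invlogit <- function(x) 1 / (1 + exp(-x))

#' Process-model log-density of the latent vital rates
#'
#' Log recruitment rates are normal around their covariate-driven means,
#' `log(rho[t]) ~ N(w_R[t,] %*% beta_R, sigma_p_R^2)`, and logit survival
#' probabilities are normal around theirs,
#' `logit(phi[i,t]) ~ N(w_S[[i]][t,] %*% beta_S[[i]], sigma_p_S[i]^2)`.
#' Densities are evaluated on the transformed (log/logit) scale on which the
#' latent states are stored, so no Jacobian terms appear.
#'
#' @param params A [lifecycle_params()].
#' @param latent A [latent_states()].
#' @param cov A [covariate_set()].
#' @return The summed log-density (a scalar).
#' @export
process_logpdf <- function(params, latent, cov) {
  if (params$sigma_p_R <= 0 || any(params$sigma_p_S <= 0))
    stop("process SDs must be strictly positive")
  if (length(params$beta_R) != ncol(cov$w_R))
    stop("beta_R length does not match the recruitment design matrix")
  lp <- sum(stats::dnorm(latent$log_rho,
                         mean = drop(cov$w_R %*% params$beta_R),
                         sd = params$sigma_p_R, log = TRUE))
  for (i in seq_len(params$n_stages - 1L)) {
    if (length(params$beta_S[[i]]) != ncol(cov$w_S[[i]]))
      stop("beta_S[[", i, "]] length does not match its design matrix")
    lp <- lp + sum(stats::dnorm(latent$logit_phi[i, ],
                                mean = drop(cov$w_S[[i]] %*% params$beta_S[[i]]),
                                sd = params$sigma_p_S[i], log = TRUE))
  }
  lp
}

#' Observation-model log-density of the abundance indices
#'
#' Each observed index is log-normal around its biased abundance:
#' `log(Y[i,t]) ~ N(log(psi[i] * N[i,t]) - sigma_o[i,t]^2 / 2,
#' sigma_o[i,t]^2)`. The `-sigma^2/2` shift makes the index unbiased for
#' `psi * N` on the natural scale. Missing entries contribute exactly zero.
#' The initial adult index `Y_init`, when present, uses the stage-`n`
#' survey's bias parameter.
#'
#' @param params A [lifecycle_params()].
#' @param N Abundance matrix from [build_abundances()] (with `"N_init"`
#'   attribute, needed when `Y_init` is present).
#' @param data An [ssm_dataset()].
#' @return The summed log-density (a scalar).
#' @export
observation_logpdf <- function(params, N, data) {
  check_psi_surveys(params, data)
  obs <- !is.na(data$Y)
  if (any(data$Y[obs] <= 0)) stop("observed index values must be positive")
  lp <- 0
  if (any(obs)) {
    psi_stage <- params$psi[data$survey_of_stage]
    idx <- which(obs, arr.ind = TRUE)
    mu <- log(psi_stage[idx[, 1]]) + log(N[obs]) - data$sigma_o[obs]^2 / 2
    lp <- sum(stats::dnorm(log(data$Y[obs]), mean = mu,
                           sd = data$sigma_o[obs], log = TRUE))
  }
  if (!is.na(data$Y_init)) {
    psi_n <- params$psi[data$survey_of_stage[data$n_stages]]
    N_init <- attr(N, "N_init")
    if (is.null(N_init)) N_init <- exp(params$log_N_init)
    mu0 <- unname(log(psi_n * N_init)) - data$sigma_o_init^2 / 2
    lp <- lp + stats::dnorm(log(data$Y_init), mean = mu0,
                            sd = data$sigma_o_init, log = TRUE)
  }
  lp
}

#' Joint negative log-density of data and latent states
#'
#' The negative of [process_logpdf()] plus [observation_logpdf()] with the
#' abundances rebuilt from the latent states. This is the integrand of the
#' Laplace-approximated marginal likelihood and the (unnormalized, minus
#' prior) Bayesian log-posterior.
#'
#' @inheritParams process_logpdf
#' @param data An [ssm_dataset()].
#' @return A scalar.
#' @export
joint_nll <- function(params, latent, data) {
  N <- build_abundances(params$log_N_init, latent, params$n_stages, data$T)
  -(process_logpdf(params, latent, data$covariates) +
      observation_logpdf(params, N, data))
}

#' Rescale the initial abundance and bias parameters jointly
#'
#' The likelihood depends on the initial abundance and the bias parameters
#' only through the products `N[n,0] * psi[i]`: multiplying `N[n,0]` by `c`
#' while dividing every `psi` by `c` leaves every observation mean unchanged.
#' This map is the exact parameter redundancy that fixing one bias parameter
#' removes.
#'
#' @param params A [lifecycle_params()].
#' @param c Positive rescaling constant.
#' @return A [lifecycle_params()] with `log_N_init + log(c)` and `psi / c`.
#' @export
rescale_params <- function(params, c) {
  if (!is.numeric(c) || length(c) != 1L || c <= 0)
    stop("rescaling constant c must be a positive scalar")
  params$log_N_init <- params$log_N_init + log(c)
  params$psi <- params$psi / c
  params
}
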