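# Shared fixtures and independent oracle routines for the test suite.

# A small random model instance (n stages, T cohorts) with one covariate per
# vital rate.
tiny_instance <- function(n = 4L, T = 5L, seed = 1L, psi = NULL,
                          sigma_o = 0.1) {
  set.seed(seed)
  cov <- covariate_set(
    w_R = cbind(1, rnorm(T)),
    w_S = replicate(n - 1L, cbind(1, rnorm(T)), simplify = FALSE))
  params <- lifecycle_params(
    n_stages = n,
    log_N_init = 10 + rnorm(1),
    beta_R = c(0.8, -0.4),
    beta_S = replicate(n - 1L, c(0.9, 1.1), simplify = FALSE),
    sigma_p_R = 0.4,
    sigma_p_S = rep(0.35, n - 1L),
    psi = psi %||% stats::setNames(runif(n, 0.2, 1.2), paste0("S", 1:n)))
  sim <- simulate_dataset(params, cov, sigma_o, seed = seed + 100L)
  list(params = params, cov = cov, data = sim$data, latent = sim$latent)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Term-by-term scalar oracle for the joint log-density: plain loops over
# every process and observation contribution, independent of the package's
# vectorized code paths.
oracle_joint_loglik <- function(params, latent, data) {
  n <- params$n_stages
  T <- data$T
  lp <- 0
  for (t in seq_len(T)) {
    mu <- sum(data$covariates$w_R[t, ] * params$beta_R)
    lp <- lp + dnorm(latent$log_rho[t], mu, params$sigma_p_R, log = TRUE)
    for (i in seq_len(n - 1L)) {
      mu <- sum(data$covariates$w_S[[i]][t, ] * params$beta_S[[i]])
      lp <- lp + dnorm(latent$logit_phi[i, t], mu, params$sigma_p_S[i],
                       log = TRUE)
    }
  }
  N <- oracle_abundances(params$log_N_init, latent)
  for (t in seq_len(T)) {
    for (i in seq_len(n)) {
      if (!is.na(data$Y[i, t])) {
        psi <- params$psi[data$survey_of_stage[i]]
        s <- data$sigma_o[i, t]
        lp <- lp + dnorm(log(data$Y[i, t]), log(psi * N[i, t]) - s^2 / 2, s,
                         log = TRUE)
      }
    }
  }
  if (!is.na(data$Y_init)) {
    psi <- params$psi[data$survey_of_stage[n]]
    s <- data$sigma_o_init
    lp <- lp + dnorm(log(data$Y_init),
                     log(psi) + params$log_N_init - s^2 / 2, s, log = TRUE)
  }
  lp
}

# Loop-free abundance oracle: every abundance is the initial adult count
# times the cumulative product of the vital rates on its path.
oracle_abundances <- function(log_N_init, latent) {
  T <- length(latent$log_rho)
  n <- nrow(latent$logit_phi) + 1L
  phi <- 1 / (1 + exp(-latent$logit_phi))
  rho <- exp(latent$log_rho)
  # path order: rho_1, phi_{1,1}, ..., phi_{n-1,1}, rho_2, ...
  u <- as.vector(rbind(rho, phi))
  cp <- exp(log_N_init) * cumprod(u)
  matrix(cp, n, T)
}

# Exact marginal likelihood of the linear-Gaussian (log-normal survival)
# variant: all latent normals and log-observations are jointly Gaussian, so
# the marginal of the observed log-indices is a multivariate normal computed
# directly from the path-dependence structure.
oracle_lognormal_marginal <- function(params, data) {
  n <- params$n_stages
  T <- data$T
  d <- T + (n - 1L) * T
  pm <- stagebias:::process_moments(params, data$covariates)
  obs <- which(!is.na(data$Y), arr.ind = TRUE)
  K <- nrow(obs)
  D <- stagebias:::obs_dependence(obs[, 1], obs[, 2], n, T)
  psi <- params$psi[data$survey_of_stage[obs[, 1]]]
  s <- data$sigma_o[cbind(obs[, 1], obs[, 2])]
  mu_y <- log(psi) + params$log_N_init + drop(D %*% pm$mean) - s^2 / 2
  Sigma <- D %*% diag(1 / pm$prec, d) %*% t(D) + diag(s^2, K)
  y <- log(data$Y[cbind(obs[, 1], obs[, 2])])
  ll <- mvtnorm::dmvnorm(y, mu_y, Sigma, log = TRUE)
  if (!is.na(data$Y_init)) {
    s0 <- data$sigma_o_init
    psi0 <- params$psi[data$survey_of_stage[n]]
    ll <- ll + dnorm(log(data$Y_init),
                     log(psi0) + params$log_N_init - s0^2 / 2, s0,
                     log = TRUE)
  }
  ll
}
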