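# Bayesian machinery: priors, sampler validity (prior recovery and an exact
# conjugate subproblem), reproducibility.

test_that("prior densities evaluate to their closed forms", {
  sc <- simulate_scenario(scenario_spec("low", biased = TRUE, T = 4, seed = 1))
  pr <- default_priors(sc$data)
  # uniform initial-abundance prior contributes -log(6) inside its support
  expect_equal(pr$log_N_init$lower, 9)
  expect_equal(pr$log_N_init$upper, 15)
  p <- sc$params
  p$log_N_init <- 13.82
  expect_equal(log_prior(p, pr, "log_N_init"), -log(6))
  # standard normal at its mean for the recruitment intercept
  p$beta_R <- c(0, p$beta_R[2])
  expect_equal(log_prior(p, pr, "beta_R_0"), -0.9189385, tolerance = 1e-6)
  # survival-coefficient precision follows 3(m+1)/pi^2 (0.61 at one covariate)
  expect_equal(pr$beta_S1_0$prec, 3 * 2 / pi^2)
  expect_equal(round(pr$beta_S1_0$prec, 2), 0.61)
  # outside support
  p$sigma_p_R <- -0.1
  expect_identical(log_prior(p, pr, "sigma_p_R"), -Inf)
})

test_that("with the likelihood off the sampler reproduces its priors", {
  sc <- simulate_scenario(scenario_spec("low", biased = FALSE, T = 8,
                                        seed = 3))
  ch <- sample_posterior(sc$data, fix_psi = c(S4 = 1), n_chains = 2,
                         n_iter = 6000, seed = 11, likelihood = FALSE)
  m <- joint_posterior_summary(ch)$marginals
  rownames(m) <- m$parameter
  # MC tolerances are generous: draws are autocorrelated
  expect_lt(abs(m["log_N_init", "mean"] - 12), 0.25)
  expect_lt(abs(m["beta_R_0", "sd"] - 1), 0.12)
  expect_lt(abs(m["beta_S1_1", "sd"] - 1 / sqrt(6 / pi^2)), 0.15)
  for (p in c("sigma_p_R", "sigma_p_S2", "psi_S2"))
    expect_lt(abs(m[p, "mean"] - 1), 0.2)
})

test_that("an exactly conjugate subproblem matches its closed-form posterior", {
  # one cohort, two stages, only the stage-1 index observed, everything
  # fixed except the recruitment intercept: the posterior of beta_R_0 is
  # Gaussian with known mean and variance
  cov <- covariate_set(w_R = matrix(1, 1, 1), w_S = list(matrix(1, 1, 1)))
  Y <- matrix(c(exp(2.3), NA), 2, 1)
  data <- ssm_dataset(Y, matrix(0.2, 2, 1), cov, c("S1", "S2"))
  ch <- sample_posterior(data, fix_psi = c(S1 = 1, S2 = 1),
                         fix_log_N_init = 0,
                         fix_params = c(sigma_p_R = 0.5, sigma_p_S1 = 0.7),
                         n_chains = 4, n_iter = 10000, seed = 5)
  x <- as.vector(ch$draws[, , "beta_R_0"])
  ystar <- 2.3 + 0.2^2 / 2
  s2 <- 0.5^2 + 0.2^2
  expect_lt(abs(mean(x) - ystar / (1 + s2)), 0.03)
  expect_lt(abs(sd(x) - sqrt(s2 / (1 + s2))), 0.03)
  # the unobserved survival intercept keeps its prior (intercept-only
  # design: precision 3/pi^2)
  y <- as.vector(ch$draws[, , "beta_S1_0"])
  expect_lt(abs(sd(y) - sqrt(pi^2 / 3)), 0.12)
})

test_that("chains are bitwise reproducible under the same seed", {
  sc <- simulate_scenario(scenario_spec("high", biased = TRUE, T = 6,
                                        seed = 13))
  a <- sample_posterior(sc$data, fix_psi = c(S4 = 1), n_chains = 2,
                        n_iter = 400, seed = 99)
  b <- sample_posterior(sc$data, fix_psi = c(S4 = 1), n_chains = 2,
                        n_iter = 400, seed = 99)
  expect_identical(a$draws, b$draws)
  c <- sample_posterior(sc$data, fix_psi = c(S4 = 1), n_chains = 2,
                        n_iter = 400, seed = 100)
  expect_false(identical(a$draws, c$draws))
})

test_that("posterior means track the MLE on well-identified data", {
  sc <- simulate_scenario(scenario_spec("high", biased = TRUE, seed = 1))
  fit <- fit_mle(sc$data, fix_psi = c(S4 = 1))
  ch <- sample_posterior(sc$data, fix_psi = c(S4 = 1), n_chains = 1,
                         n_iter = 8000, seed = 21)
  m <- joint_posterior_summary(ch)$marginals
  rownames(m) <- m$parameter
  # per parameter: |posterior mean - MLE| < 2 SE (Wald SE from the fit),
  # plus a 0.1 allowance for the Monte-Carlo error of the mean at this
  # deliberately short chain length
  comp <- list(c("beta_R_0", "beta_R_0"), c("beta_R_1", "beta_R_1"),
               c("beta_S1_1", "beta_S1_1"), c("beta_S2_0", "beta_S2_0"))
  for (pp in comp) {
    se <- sqrt(fit$vcov[pp[1], pp[1]])
    expect_lt(abs(m[pp[2], "mean"] - fit$par[pp[1]]), 2 * se + 0.1)
  }
  # natural-scale bias parameters agree with exp of the link-scale MLE
  for (s in c("S1", "S2")) {
    mle_psi <- exp(fit$par[paste0("log_psi_", s)])
    expect_lt(abs(m[paste0("psi_", s), "mean"] - mle_psi) / mle_psi, 0.2)
  }
})
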