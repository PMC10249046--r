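# Maximum-likelihood fitting, model comparison and profiles.

fit_cache <- new.env()
cached_fit <- function() {
  if (is.null(fit_cache$fit)) {
    fit_cache$sc <- simulate_scenario(scenario_spec("high", biased = TRUE,
                                                    seed = 1))
    fit_cache$fit <- fit_mle(fit_cache$sc$data, fix_psi = c(S4 = 1))
  }
  list(sc = fit_cache$sc, fit = fit_cache$fit)
}

test_that("fitting refuses non-identifiable configurations", {
  sc <- simulate_scenario(scenario_spec("low", biased = TRUE, T = 6, seed = 2))
  expect_error(fit_mle(sc$data), "identifiable")
  expect_error(sample_posterior(sc$data, n_iter = 10), "identifiable")
})

test_that("near-deterministic data recovers the coefficients almost exactly", {
  spec <- scenario_spec("low", biased = FALSE, T = 20)
  p <- preset_params(spec)
  p$sigma_p_R <- 0.01
  p$sigma_p_S <- rep(0.01, 3)
  cov <- simulate_covariates(20, 4, 1, seed = 41)
  sim <- simulate_dataset(p, cov, 0.005, seed = 42)
  fit <- fit_mle(sim$data, fix_psi = c(S1 = 1, S2 = 1, S3 = 1, S4 = 1))
  expect_true(fit$converged)
  th <- fit$theta_hat
  expect_lt(abs(th$beta_R[1] - 1) / 1, 0.01)
  expect_lt(abs(th$beta_R[2] - (-0.5)) / 0.5, 0.01)
  for (i in 1:3) {
    expect_lt(abs(th$beta_S[[i]][1] - 1), 0.02)
    expect_lt(abs(th$beta_S[[i]][2] - 1.3) / 1.3, 0.02)
  }
})

test_that("estimates land on the rescaled truth when the reference bias is misfixed", {
  cf <- cached_fit()
  fit <- cf$fit
  true <- cf$sc$params
  expect_true(fit$converged && fit$hessian_pd)
  adj <- adjusted_true_values(true, "S4", 1)
  # psi_4 truly 0.5 but fixed at 1: N-hat near N0/2, psi-hat near 2 psi
  expect_lt(abs(fit$theta_hat$log_N_init - adj$log_N_init), 0.15)
  for (s in c("S1", "S2", "S3"))
    expect_lt(abs(fit$theta_hat$psi[s] - adj$psi[s]) / adj$psi[s], 0.15)
  # state-process coefficients estimated near truth despite the misfixed bias
  expect_lt(abs(fit$theta_hat$beta_R[2] - true$beta_R[2]), 0.2)
})

test_that("a fully constrained fit has no free parameters and AICc = -2 loglik", {
  spec <- scenario_spec("low", biased = TRUE, T = 6)
  sc <- simulate_scenario(scenario_spec("low", biased = TRUE, T = 6, seed = 9))
  p <- sc$params
  fit <- fit_mle(sc$data, fix_psi = stats::setNames(unname(p$psi), names(p$psi)),
                 fix_log_N_init = p$log_N_init,
                 fix_coords = c(
                   beta_R_0 = p$beta_R[1], beta_R_1 = p$beta_R[2],
                   beta_S1_0 = 1, beta_S1_1 = 1.3, beta_S2_0 = 1,
                   beta_S2_1 = 1.3, beta_S3_0 = 1, beta_S3_1 = 1.3,
                   log_sigma_p_R = log(0.5), log_sigma_p_S1 = log(0.5),
                   log_sigma_p_S2 = log(0.5), log_sigma_p_S3 = log(0.5)))
  expect_length(fit$par, 0)
  expect_equal(aicc(fit), -2 * fit$loglik)
})

test_that("AICc applies the small-sample correction and approaches AIC", {
  cf <- cached_fit()
  fit <- cf$fit
  k <- length(fit$par)
  n <- fit$n_obs
  expect_equal(aicc(fit),
               -2 * fit$loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1))
  # inflate n_obs: correction vanishes
  fit_big <- fit
  fit_big$n_obs <- 1e9L
  expect_equal(aicc(fit_big), -2 * fit$loglik + 2 * k, tolerance = 1e-6)
  fit_small <- fit
  fit_small$n_obs <- k + 1L
  expect_error(aicc(fit_small), "undefined")
})

test_that("likelihood-ratio arithmetic and edge cases behave", {
  out <- lrt(-183.24, -120.21, df = 2)
  expect_equal(unname(out$statistic), 126.06)
  expect_lt(out$p.value, 0.01)
  expect_error(lrt(-10, -9), "df must be given")
  same <- lrt(-50, -50, df = 1)
  expect_equal(unname(same$statistic), 0)
  expect_equal(same$p.value, 1)
  expect_warning(lrt(-49, -50, df = 1), "lower log-likelihood")
})

test_that("nesting is inferred from free-parameter sets", {
  sc <- simulate_scenario(scenario_spec("high", biased = TRUE, T = 10,
                                        seed = 5))
  fit_full <- fit_mle(sc$data, fix_psi = c(S4 = 1))
  fit_nested <- fit_mle(sc$data,
                        fix_psi = c(S1 = 1, S2 = 1, S3 = 1, S4 = 1))
  out <- lrt(fit_nested, fit_full)
  expect_equal(unname(out$parameter), 3)
  expect_gte(unname(out$statistic), 0)
  expect_error(lrt(fit_full, fit_nested), "not nested")
})

test_that("profiles peak at the MLE and respect the constrained-optimum bound", {
  cf <- cached_fit()
  fit <- cf$fit
  est <- fit$par["beta_R_1"]
  se <- sqrt(fit$vcov["beta_R_1", "beta_R_1"])
  grid <- est + se * seq(-2.5, 2.5, length.out = 9)
  pr <- profile(fit, "beta_R_1", grid)
  expect_true(all(pr$converged))
  expect_true(all(pr$loglik <= fit$loglik + 1e-6))
  # at (essentially) the MLE the profile recovers the full maximum
  pr_at <- profile(fit, "beta_R_1", est)
  expect_equal(pr_at$loglik, fit$loglik, tolerance = 1e-5)
  # near-quadratic likelihood: the 1.92-drop points sit near +-1.96 SE
  prof_fun <- stats::approxfun(pr$beta_R_1, fit$loglik - pr$loglik)
  lo <- stats::uniroot(function(x) prof_fun(x) - 1.92, c(est - 2.4 * se, est))$root
  hi <- stats::uniroot(function(x) prof_fun(x) - 1.92, c(est, est + 2.4 * se))$root
  expect_lt(abs((est - lo) - 1.96 * se) / (1.96 * se), 0.10)
  expect_lt(abs((hi - est) - 1.96 * se) / (1.96 * se), 0.10)
})
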