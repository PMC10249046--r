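# One-step-ahead prediction residuals: calibration under the true model,
# systematic drift under bias misspecification, degeneracy without noise.

test_that("residuals are calibrated when the fitted model is true", {
  sc <- simulate_scenario(scenario_spec("high", biased = FALSE, seed = 8))
  fit <- fit_mle(sc$data, fix_psi = c(S1 = 1, S2 = 1, S3 = 1, S4 = 1))
  r <- osa_residuals(fit)
  expect_equal(nrow(r), n_obs(sc$data))
  N <- nrow(r)
  expect_lt(abs(mean(r$residual)), 3 / sqrt(N))
  expect_gt(var(r$residual), 0.8)
  expect_lt(var(r$residual), 1.2)
  # prediction order: initial adult index first, then cohort by cohort
  expect_equal(r$cohort[1], 0L)
  expect_true(all(diff(r$cohort) >= 0))
})

test_that("ignoring a strong true bias leaves a systematic residual sign", {
  # data biased (psi_2 = 0.1 most extreme); model fixes all psi at 1:
  # the misspecified stages' indices are systematically over-predicted
  sc <- simulate_scenario(scenario_spec("high", biased = TRUE, seed = 9))
  fit <- fit_mle(sc$data, fix_psi = c(S1 = 1, S2 = 1, S3 = 1, S4 = 1))
  r <- osa_residuals(fit)
  m2 <- mean(r$residual[r$stage == 2 & r$cohort > 0])
  expect_lt(m2, -0.5)
  # the correctly anchored model shows no such drift
  fit_ok <- fit_mle(sc$data, fix_psi = c(S4 = 1))
  r_ok <- osa_residuals(fit_ok)
  expect_lt(abs(mean(r_ok$residual[r_ok$stage == 2 & r_ok$cohort > 0])), 0.5)
})

test_that("data on the exact deterministic path produces near-zero residuals", {
  # indices placed exactly at psi * N with rates at their covariate-driven
  # means: every one-step-ahead prediction coincides with the observation
  p <- preset_params(scenario_spec("low", biased = TRUE, T = 8))
  cov <- simulate_covariates(8, 4, 1, seed = 51)
  lat <- latent_states(drop(cov$w_R %*% p$beta_R),
                       t(vapply(1:3, function(i)
                         drop(cov$w_S[[i]] %*% p$beta_S[[i]]), numeric(8))))
  N <- build_abundances(p$log_N_init, lat, 4, 8)
  psi_stage <- p$psi[paste0("S", 1:4)]
  data <- ssm_dataset(psi_stage * N, matrix(0.05, 4, 8), cov,
                      paste0("S", 1:4),
                      Y_init = unname(psi_stage[4]) * exp(p$log_N_init),
                      sigma_o_init = 0.05)
  fit <- structure(list(theta_hat = p, data = data), class = "ssm_fit")
  r <- osa_residuals(fit)
  expect_lt(max(abs(r$residual)), 0.2)
})

test_that("missing observations are skipped", {
  sc <- simulate_scenario(scenario_spec("low", biased = FALSE, T = 10,
                                        seed = 12))
  Y <- sc$data$Y
  Y[1, 1:4] <- NA  # early gap in the first survey
  data <- ssm_dataset(Y, sc$data$sigma_o, sc$data$covariates,
                      sc$data$survey_of_stage, sc$data$Y_init,
                      sc$data$sigma_o_init)
  fit <- fit_mle(data, fix_psi = c(S1 = 1, S2 = 1, S3 = 1, S4 = 1))
  r <- osa_residuals(fit)
  expect_equal(nrow(r), n_obs(data))
  expect_false(any(r$stage == 1 & r$cohort %in% 1:4))
})
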