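test_that("scenario presets carry the documented parameter values", {
  p <- preset_params(scenario_spec("low", biased = TRUE))
  expect_equal(p$log_N_init, 13.82)
  expect_equal(p$beta_R, c(1.00, -0.50))
  for (b in p$beta_S) expect_equal(b, c(1.00, 1.30))
  expect_equal(p$sigma_p_R, 0.50)
  expect_equal(p$sigma_p_S, rep(0.50, 3))
  expect_equal(unname(p$psi), c(0.20, 0.10, 0.40, 0.50))
  expect_equal(attr(p, "sigma_o"), 0.10)

  h <- preset_params(scenario_spec("high", biased = TRUE))
  expect_equal(h$beta_R, c(1.75, -1.00))
  for (b in h$beta_S) expect_equal(b, c(1.00, 2.00))
  expect_equal(h$sigma_p_R, 0.25)
  expect_equal(attr(h, "sigma_o"), 0.05)
  expect_equal(unname(h$psi), c(0.20, 0.10, 0.40, 0.50))

  u <- preset_params(scenario_spec("low", biased = FALSE))
  expect_equal(unname(u$psi), rep(1, 4))
  expect_equal(u$beta_R, p$beta_R)
})

test_that("covariate simulation is shaped, seeded and centered", {
  cov <- simulate_covariates(20, 4, 1, seed = 5)
  expect_equal(dim(cov$w_R), c(20L, 2L))
  expect_true(all(cov$w_R[, 1] == 1))
  expect_length(cov$w_S, 3)
  cov2 <- simulate_covariates(20, 4, 1, seed = 5)
  expect_identical(cov, cov2)
  big <- simulate_covariates(1e4, 2, 1, seed = 9)
  expect_lt(abs(mean(big$w_R[, 2])), 4 / sqrt(1e4))
})

test_that("default scenario yields the full 4 x 20 latent state grid", {
  sc <- simulate_scenario(scenario_spec("low", biased = TRUE, seed = 2))
  expect_equal(dim(sc$data$Y), c(4L, 20L))
  expect_equal(length(sc$latent$log_rho) + length(sc$latent$logit_phi), 80L)
  N <- build_abundances(sc$params$log_N_init, sc$latent, 4, 20)
  expect_length(N, 80L)
  expect_true(all(is.finite(N)) && all(N > 0))
  expect_false(is.na(sc$data$Y_init))
})

test_that("degenerate noise collapses indices onto psi * N and rates onto their medians", {
  spec <- scenario_spec("low", biased = TRUE, T = 10)
  p <- preset_params(spec)
  p$sigma_p_R <- 1e-10
  p$sigma_p_S <- rep(1e-10, 3)
  cov <- simulate_covariates(10, 4, 1, seed = 3)
  sim <- simulate_dataset(p, cov, 1e-10, seed = 4)
  N <- build_abundances(p$log_N_init, sim$latent, 4, 10)
  psi_stage <- p$psi[sim$data$survey_of_stage]
  expect_equal(unname(sim$data$Y), unname(psi_stage * N), tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(sim$latent$log_rho, drop(cov$w_R %*% p$beta_R),
               tolerance = 1e-6)
})

test_that("simulated vital rates reproduce the process SD across replicates", {
  spec <- scenario_spec("low", biased = TRUE, T = 1)
  p <- preset_params(spec)
  cov <- covariate_set(w_R = matrix(c(1, 0.3), 1), w_S = list(
    matrix(c(1, 0.1), 1), matrix(c(1, 0.1), 1), matrix(c(1, 0.1), 1)))
  draws <- vapply(1:2000, function(k)
    simulate_dataset(p, cov, 0.1, seed = k)$latent$log_rho, 0)
  expect_lt(abs(sd(draws) - p$sigma_p_R) / p$sigma_p_R, 0.05)
  # simulated survival probabilities stay inside (0,1) and abundances positive
  sim <- simulate_dataset(p, cov, 0.1, seed = 1)
  phi <- plogis(sim$latent$logit_phi)
  expect_true(all(phi > 0 & phi < 1))
})

test_that("simulation is reproducible under a fixed seed", {
  spec <- scenario_spec("high", biased = FALSE, seed = 77)
  a <- simulate_scenario(spec)
  b <- simulate_scenario(spec)
  expect_identical(a$data$Y, b$data$Y)
  expect_identical(a$latent, b$latent)
})
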