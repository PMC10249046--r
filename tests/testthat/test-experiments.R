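# Simulation-experiment machinery: adjusted truths, the simulate-and-refit
# study loop, vital-rate curves, and the intercept grid scan.

test_that("adjusted true values rescale the initial abundance and biases", {
  p <- preset_params(scenario_spec("low", biased = TRUE))
  adj <- adjusted_true_values(p, "S4", 1)
  # psi_4 = 0.5 misfixed at 1: free biases double, initial abundance halves
  expect_equal(unname(adj$psi), c(0.40, 0.20, 0.80))
  expect_equal(adj$N_init, exp(13.82) / 2)
  expect_equal(adj$log_N_init, 13.82 + log(0.5))
  # fixing at the true value is the identity
  id <- adjusted_true_values(p, "S4", 0.5)
  expect_equal(id$psi, p$psi[c("S1", "S2", "S3")])
  expect_equal(id$N_init, exp(13.82))
  # ratios of adjusted biases equal ratios of the true biases
  expect_equal(unname(adj$psi["S1"] / adj$psi["S2"]),
               unname(p$psi["S1"] / p$psi["S2"]))
  expect_error(adjusted_true_values(p, "S9"), "unknown")
  expect_error(adjusted_true_values(p, "S4", -1), "positive")
})

test_that("a single-replicate study completes and reports its bookkeeping", {
  st <- run_bias_study(1, scenario_spec("low", biased = TRUE, T = 12),
                       model = "fix_ref", seed = 3)
  expect_s3_class(st, "sim_study")
  expect_equal(st$n_reps, 1L)
  expect_equal(nrow(st$estimates), 1L)
  expect_true(all(c("N_init", "beta_R_1", "sigma_p_S3", "psi_S1") %in%
                    st$summary$parameter))
  # fix_ref scores against the adjusted truths
  expect_equal(st$summary$true[st$summary$parameter == "psi_S1"], 0.40)
  expect_equal(st$summary$true[st$summary$parameter == "N_init"],
               exp(13.82) / 2)
  # fix_all scores against the raw truths and estimates no psi
  st0 <- run_bias_study(1, scenario_spec("low", biased = FALSE, T = 12),
                        model = "fix_all", seed = 3)
  expect_false(any(grepl("^psi_", st0$summary$parameter)))
  expect_equal(st0$summary$true[st0$summary$parameter == "N_init"],
               exp(13.82))
})

test_that("vital-rate curves collapse without process noise and obey their links", {
  sc <- simulate_scenario(scenario_spec("high", biased = TRUE, seed = 1))
  fit <- fit_mle(sc$data, fix_psi = c(S4 = 1))
  # survival bands inside (0,1), ordered band edges
  cv <- vital_rate_curves(fit, n_draws = 2000, seed = 2)
  sv <- cv[cv$vital_rate != "R", ]
  expect_true(all(sv$lo >= 0 & sv$hi <= 1))
  expect_true(all(cv$lo <= cv$mean & cv$mean <= cv$hi))
  # sigma -> 0: band collapses onto the deterministic inverse-link curve
  fit0 <- fit
  fit0$theta_hat$sigma_p_R <- 1e-12
  fit0$theta_hat$sigma_p_S <- rep(1e-12, 3)
  cv0 <- vital_rate_curves(fit0, n_draws = 200, seed = 3)
  expect_equal(cv0$lo, cv0$hi, tolerance = 1e-6)
  r0 <- cv0[cv0$vital_rate == "R", ]
  b <- fit$theta_hat$beta_R
  expect_equal(r0$mean, exp(b[1] + b[2] * r0$x), tolerance = 1e-6)
  # log-normal mean identity: mean of draws -> exp(eta + sigma^2/2)
  r <- cv[cv$vital_rate == "R", ]
  eta <- b[1] + b[2] * r$x
  expected <- exp(eta + fit$theta_hat$sigma_p_R^2 / 2)
  expect_lt(max(abs(r$mean - expected) / expected), 0.1)
})

test_that("the intercept grid scan retains the MLE and tightens with alpha", {
  sc <- simulate_scenario(scenario_spec("high", biased = TRUE, T = 12,
                                        seed = 4))
  fit <- fit_mle(sc$data, fix_psi = c(S4 = 1))
  est <- fit$par[c("beta_R_0", "beta_S1_0")]
  bounds <- list(est[1] + c(-1, 1), est[2] + c(-1.5, 1.5))
  gs <- intercept_grid_scan(fit, c("beta_R_0", "beta_S1_0"), bounds,
                            grid_n = 5, alpha = 0.05)
  expect_equal(nrow(gs$points), 25L)
  # the grid point nearest the MLE is retained (deviance near zero)
  d2 <- (gs$points$beta_R_0 - est[1])^2 + (gs$points$beta_S1_0 - est[2])^2
  expect_true(gs$points$retained[which.min(d2)])
  expect_true(all(gs$points$deviance[gs$points$converged] > -1e-6))
  # alpha -> 1 keeps only (near-)MLE points
  thr0 <- stats::qchisq(1 - 0.9999, df = 2)
  kept <- gs$points$converged & gs$points$deviance <= thr0
  expect_lte(sum(kept), sum(gs$points$retained))
})

test_that("a misfixed reference bias elongates the retained intercept cloud", {
  # low-information biased data with psi_4 misfixed at 1: the likelihood
  # ridge couples the recruitment and early-survival intercepts, so the
  # retained grid cloud is far from spherical
  sc <- simulate_scenario(scenario_spec("low", biased = TRUE, seed = 6))
  fit <- fit_mle(sc$data, fix_psi = c(S4 = 1))
  est <- fit$par[c("beta_R_0", "beta_S1_0", "beta_S2_0")]
  bounds <- lapply(seq_along(est), function(j) est[j] + c(-1.2, 1.2))
  gs <- intercept_grid_scan(fit, names(est), bounds, grid_n = 4,
                            alpha = 0.05)
  pts <- gs$points[gs$points$retained, names(est)]
  expect_gt(nrow(pts), 3)
  ev <- eigen(stats::cov(as.matrix(pts)), symmetric = TRUE,
              only.values = TRUE)$values
  expect_gt(ev[1] / max(ev[length(ev)], 1e-12), 3)
})
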