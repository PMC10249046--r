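# The inner (latent-block) optimization and the Laplace marginal, checked
# against finite differences, a linear-Gaussian closed form, and numerical
# quadrature.

test_that("analytic latent gradient and Hessian match finite differences", {
  skip_if_not_installed("numDeriv")
  ti <- tiny_instance(n = 4, T = 4, seed = 21)
  u <- stagebias:::pack_latent(ti$latent)
  f <- function(u) stagebias:::joint_nll_u_deriv(ti$params, u, ti$data)$value
  d <- stagebias:::joint_nll_u_deriv(ti$params, u, ti$data)
  expect_equal(d$value, joint_nll(ti$params, ti$latent, ti$data),
               tolerance = 1e-10)
  expect_equal(d$gradient, numDeriv::grad(f, u), tolerance = 1e-6)
  expect_equal(d$hessian, numDeriv::hessian(f, u), tolerance = 1e-4)
})

test_that("inner Newton reaches gradient tolerance on random instances", {
  for (seed in c(2, 9)) {
    ti <- tiny_instance(n = 4, T = 6, seed = seed)
    im <- inner_mode(ti$params, ti$data)
    expect_true(im$converged)
    expect_lte(im$grad_norm, 1e-8)
    # the mode's Hessian is positive definite
    expect_true(all(eigen(im$hessian, symmetric = TRUE,
                          only.values = TRUE)$values > 0))
  }
})

test_that("the linear-Gaussian variant is solved in essentially one Newton step", {
  # with log-normal survival the joint density is exactly quadratic in the
  # latent block, so Newton lands on the mode immediately
  ti <- tiny_instance(n = 3, T = 5, seed = 4)
  im <- inner_mode(ti$params, ti$data, surv_lognormal = TRUE)
  expect_true(im$converged)
  expect_lte(im$iterations, 2L)
})

test_that("with tiny observation noise the mode reproduces the data-implied states", {
  spec <- scenario_spec("low", biased = TRUE, T = 8)
  p <- preset_params(spec)
  cov <- simulate_covariates(8, 4, 1, seed = 31)
  sim <- simulate_dataset(p, cov, 1e-3, seed = 32)
  im <- inner_mode(p, sim$data, tol = 1e-6)
  expect_true(im$converged)
  expect_equal(im$latent$log_rho, sim$latent$log_rho, tolerance = 1e-2)
  expect_equal(im$latent$logit_phi, sim$latent$logit_phi, tolerance = 5e-2)
})

test_that("Laplace marginal is exact for the linear-Gaussian variant (closed-form oracle)", {
  skip_if_not_installed("mvtnorm")
  for (seed in c(6, 15)) {
    ti <- tiny_instance(n = 3, T = 5, seed = seed)
    marg <- marginal_nll(ti$params, ti$data, surv_lognormal = TRUE)
    oracle <- -oracle_lognormal_marginal(ti$params, ti$data)
    expect_equal(as.numeric(marg), oracle, tolerance = 1e-8)
  }
})

test_that("Laplace marginal approximates exact quadrature on a one-cohort model", {
  # n = 2, T = 1: two latent variables, integrable by nested quadrature
  set.seed(8)
  cov <- covariate_set(w_R = matrix(1, 1, 1), w_S = list(matrix(1, 1, 1)))
  p <- lifecycle_params(2, log(500), beta_R = 0.5, beta_S = list(0.8),
                        sigma_p_R = 0.4, sigma_p_S = 0.5,
                        psi = c(S1 = 0.6, S2 = 1))
  sim <- simulate_dataset(p, cov, 0.15, seed = 9)
  lap <- as.numeric(marginal_nll(p, sim$data))
  lik <- function(lr, lp) {
    vapply(seq_along(lr), function(k) {
      lat <- latent_states(lr[k], matrix(lp[k], 1, 1))
      exp(-joint_nll(p, lat, sim$data))
    }, 0)
  }
  inner <- function(lr) vapply(lr, function(r)
    integrate(function(lp) lik(rep(r, length(lp)), lp), -4, 6,
              rel.tol = 1e-10)$value, 0)
  exact <- -log(integrate(inner, 0.5 - 8, 0.5 + 8, rel.tol = 1e-8)$value)
  expect_lt(abs(lap - exact) / abs(exact), 0.01)
})

test_that("the Laplace marginal agrees with the compiled implementation", {
  ti <- tiny_instance(n = 4, T = 10, seed = 12)
  obj <- TMB::MakeADFun(
    data = stagebias:::tmb_data_list(ti$data),
    parameters = stagebias:::tmb_par_list(ti$params, ti$data),
    random = c("log_rho", "logit_phi"), DLL = "stagebias", silent = TRUE)
  expect_equal(as.numeric(marginal_nll(ti$params, ti$data)),
               as.numeric(obj$fn(obj$par)), tolerance = 1e-6)
})

test_that("marginal likelihood is invariant under rescaling when every bias is free", {
  ti <- tiny_instance(n = 3, T = 6, seed = 18)
  base <- as.numeric(marginal_nll(ti$params, ti$data))
  resc <- as.numeric(marginal_nll(rescale_params(ti$params, 3), ti$data))
  expect_equal(base, resc, tolerance = 1e-8)
})
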