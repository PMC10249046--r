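test_that("abundance recursion matches identity dynamics and direct arithmetic", {
  # identity dynamics: all rates 1 keeps every abundance at N_init
  lat <- latent_states(rep(0, 3), matrix(qlogis(1 - 1e-12), 3, 3))
  N <- build_abundances(log(100), lat, 4, 3)
  expect_equal(unname(N), matrix(100, 4, 3), tolerance = 1e-6,
               ignore_attr = TRUE)

  # one step by hand: N1 = rho * N_init, N2 = phi1 * N1
  lat <- latent_states(log(0.5), matrix(qlogis(0.5), 1, 1))
  N <- build_abundances(log(100), lat, 2, 1)
  expect_equal(N[1, 1], 50)
  expect_equal(N[2, 1], 25)
  expect_equal(attr(N, "N_init"), 100)
})

test_that("abundances agree with the cumulative-product oracle", {
  set.seed(42)
  for (rep in 1:5) {
    T <- sample(3:20, 1)
    n <- sample(2:5, 1)
    lat <- latent_states(rnorm(T), matrix(rnorm((n - 1) * T), n - 1, T))
    N <- build_abundances(rnorm(1, 8), lat, n, T)
    expect_equal(unname(N),
                 unname(oracle_abundances(log(attr(N, "N_init")), lat)),
                 tolerance = 1e-10, ignore_attr = TRUE)
    # survival probabilities in (0,1) imply within-cohort monotone decline
    expect_true(all(N[-1, ] <= N[-n, ]))
  }
})

test_that("abundance recursion validates dimensions", {
  lat <- latent_states(rep(0, 3), matrix(0, 2, 3))
  expect_error(build_abundances(0, lat, 4, 3), "dimensions")
  expect_error(build_abundances(0, lat, 3, 4), "dimensions")
})

test_that("process density equals the standard normal at its mean and scales correctly", {
  cov <- covariate_set(w_R = matrix(1, 1, 1), w_S = list(matrix(1, 1, 1)))
  p <- lifecycle_params(2, 0, beta_R = 0, beta_S = list(0), sigma_p_R = 1,
                        sigma_p_S = 1e6, psi = c(1, 1))
  lat <- latent_states(0, matrix(0, 1, 1))
  base <- process_logpdf(p, lat, cov)
  # survival term is ~flat at SD 1e6; the recruitment term is the standard
  # normal at its mean
  expect_equal(base - dnorm(0, 0, 1e6, log = TRUE), -0.9189385, tolerance = 1e-6)

  p2 <- p
  p2$sigma_p_R <- 2
  expect_equal(process_logpdf(p2, lat, cov) - base, -log(2), tolerance = 1e-12)
})

test_that("observation density matches its predictive-mean value and empty-sum case", {
  cov <- covariate_set(w_R = matrix(1, 1, 1), w_S = list(matrix(1, 1, 1)))
  p <- lifecycle_params(2, 0, beta_R = 0, beta_S = list(0), sigma_p_R = 1,
                        sigma_p_S = 1, psi = c(S1 = 1, S2 = 1))
  N <- matrix(1, 2, 1)
  # observation exactly at the log-scale predictive mean
  data <- ssm_dataset(matrix(c(exp(-0.005), NA), 2, 1), matrix(0.1, 2, 1),
                      cov, c("S1", "S2"))
  expect_equal(observation_logpdf(p, N, data), -0.9189385 - log(0.1),
               tolerance = 1e-6)
  # all missing: exactly zero
  data0 <- ssm_dataset(matrix(NA_real_, 2, 1), matrix(0.1, 2, 1), cov,
                       c("S1", "S2"))
  expect_identical(observation_logpdf(p, N, data0), 0)
})

test_that("simulated indices are unbiased for psi * N on the natural scale", {
  # Monte-Carlo check of the -sigma^2/2 mean correction
  set.seed(7)
  psi <- 0.4
  N <- 1000
  sigma <- 0.5
  n_mc <- 1e5
  y <- exp(rnorm(n_mc, log(psi * N) - sigma^2 / 2, sigma))
  se <- sd(y) / sqrt(n_mc)
  expect_lt(abs(mean(y) - psi * N), 3 * se)
})

test_that("joint density equals its definition and the term-by-term oracle", {
  ti <- tiny_instance(n = 4, T = 3, seed = 11)
  N <- build_abundances(ti$params$log_N_init, ti$latent, 4, ti$data$T)
  expect_equal(joint_nll(ti$params, ti$latent, ti$data),
               -(process_logpdf(ti$params, ti$latent, ti$cov) +
                   observation_logpdf(ti$params, N, ti$data)))
  expect_equal(-joint_nll(ti$params, ti$latent, ti$data),
               oracle_joint_loglik(ti$params, ti$latent, ti$data),
               tolerance = 1e-10)
  # separate densities also match the oracle when split
  expect_equal(process_logpdf(ti$params, ti$latent, ti$cov) +
                 observation_logpdf(ti$params, N, ti$data),
               oracle_joint_loglik(ti$params, ti$latent, ti$data),
               tolerance = 1e-10)
})

test_that("compiled and interpreted joint densities agree", {
  ti <- tiny_instance(n = 4, T = 6, seed = 3)
  obj <- TMB::MakeADFun(
    data = stagebias:::tmb_data_list(ti$data),
    parameters = stagebias:::tmb_par_list(ti$params, ti$data, ti$latent),
    DLL = "stagebias", silent = TRUE)
  expect_equal(joint_nll(ti$params, ti$latent, ti$data),
               unname(obj$fn(obj$par)), tolerance = 1e-9)
})

test_that("rescaling the initial abundance against the biases is exact", {
  p <- lifecycle_params(4, 10, beta_R = c(1, -0.5),
                        beta_S = replicate(3, c(1, 1.3), simplify = FALSE),
                        sigma_p_R = 0.5, sigma_p_S = rep(0.5, 3),
                        psi = c(S1 = 0.2, S2 = 0.1, S3 = 0.4, S4 = 0.5))
  expect_equal(rescale_params(p, 1), p)
  p2 <- rescale_params(p, 2)
  expect_equal(unname(p2$psi), c(0.1, 0.05, 0.2, 0.25))
  expect_equal(p2$log_N_init, 10 + log(2))
  expect_error(rescale_params(p, -1), "positive")
  expect_error(rescale_params(p, 0), "positive")
})

test_that("joint likelihood is invariant under the bias rescaling map", {
  for (seed in 1:4) {
    ti <- tiny_instance(n = 4, T = 8, seed = seed)
    base <- joint_nll(ti$params, ti$latent, ti$data)
    for (cc in c(0.1, 0.7, 2, 13.5)) {
      shifted <- joint_nll(rescale_params(ti$params, cc), ti$latent, ti$data)
      expect_lt(abs(shifted - base), 1e-10 * abs(base))
    }
  }
})

test_that("domain errors are raised for invalid inputs", {
  ti <- tiny_instance(n = 3, T = 3, seed = 5)
  bad <- ti$params
  bad$sigma_p_R <- -0.1
  expect_error(process_logpdf(bad, ti$latent, ti$cov), "positive")
  expect_error(
    ssm_dataset(matrix(-1, 3, 3), matrix(0.1, 3, 3), ti$cov,
                paste0("S", 1:3)),
    "positive")
  expect_error(lifecycle_params(1, 0, 0, list(), 1, numeric(0), 1), "n_stages")
})
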