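# Pure-R Laplace machinery: analytic derivatives of the joint negative
# log-density with respect to the latent vital rates, an inner Newton
# optimizer, and the Laplace-approximated marginal likelihood. This path is
# independent of the compiled TMB objective and backs the one-step-ahead
# residuals and the oracle cross-checks.

# Latent vector layout: u = c(log_rho[1..T], logit_phi stacked column-major
# so that coordinate T + (t-1)(n-1) + i is stage-transition i of cohort t.
pack_latent <- function(latent) c(latent$log_rho, as.vector(latent$logit_phi))

unpack_latent <- function(u, n, T) {
  latent_states(u[seq_len(T)], matrix(u[-seq_len(T)], n - 1L, T))
}

# Joint nll with optional log-normal-survival variant (the latent survival
# slots then hold log(phi) and enter the recursion linearly, which makes the
# whole model linear-Gaussian and the Laplace approximation exact).
joint_nll_variant <- function(params, latent, data, surv_lognormal = FALSE) {
  log_phi_fun <- if (surv_lognormal) identity else log_invlogit
  logN <- log_abundances(params$log_N_init, latent$log_rho, latent$logit_phi,
                         log_phi_fun)
  N <- exp(logN)
  attr(N, "N_init") <- exp(params$log_N_init)
  -(process_logpdf(params, latent, data$covariates) +
      observation_logpdf(params, N, data))
}

# Process means and precisions per latent coordinate, in pack_latent order.
process_moments <- function(params, cov) {
  n <- params$n_stages
  mu_S <- matrix(vapply(seq_len(n - 1L),
                        function(i) drop(cov$w_S[[i]] %*% params$beta_S[[i]]),
                        numeric(cov$T)), nrow = cov$T) # T x (n-1)
  m <- c(drop(cov$w_R %*% params$beta_R), as.vector(t(mu_S)))
  prec <- c(rep(1 / params$sigma_p_R^2, cov$T),
            rep(1 / params$sigma_p_S^2, cov$T))
  list(mean = m, prec = prec)
}

# 0/1 dependence matrix of observation means on latent coordinates: row k is
# observation (i_k, t_k); mu_k depends on every recruitment up to cohort t_k,
# every survival of earlier cohorts, and this cohort's survivals below i_k.
obs_dependence <- function(stage, cohort, n, T) {
  K <- length(stage)
  d <- T + (n - 1L) * T
  D <- matrix(0, K, d)
  lat_cohort <- c(seq_len(T), rep(seq_len(T), each = n - 1L))
  lat_stage <- c(rep(0L, T), rep(seq_len(n - 1L), T))
  for (k in seq_len(K)) {
    dep_rec <- lat_stage == 0L & lat_cohort <= cohort[k]
    dep_sur <- lat_stage > 0L & (lat_cohort < cohort[k] |
                                   (lat_cohort == cohort[k] &
                                      lat_stage < stage[k]))
    D[k, ] <- as.numeric(dep_rec | dep_sur)
  }
  D
}

# Value, gradient and Hessian of the joint nll in the latent block.
# dep_cache: optional precomputed obs_dependence matrix for the full
# observation set (it depends only on the missingness pattern).
joint_nll_u_deriv <- function(params, u, data, surv_lognormal = FALSE,
                              obs_mask = NULL, dep_cache = NULL) {
  n <- params$n_stages
  T <- data$T
  latent <- unpack_latent(u, n, T)
  pm <- process_moments(params, data$covariates)
  obs <- if (is.null(obs_mask)) !is.na(data$Y) else obs_mask & !is.na(data$Y)

  log_phi_fun <- if (surv_lognormal) identity else log_invlogit
  logN <- log_abundances(params$log_N_init, latent$log_rho,
                         latent$logit_phi, log_phi_fun)
  # value
  psi_stage <- params$psi[data$survey_of_stage]
  val <- sum((u - pm$mean)^2 * pm$prec) / 2 +
    sum(log(1 / sqrt(pm$prec))) + length(u) * log(2 * pi) / 2
  g <- (u - pm$mean) * pm$prec
  H_diag <- pm$prec

  K <- sum(obs)
  if (K > 0) {
    idx <- which(obs, arr.ind = TRUE)
    i_k <- idx[, 1]; t_k <- idx[, 2]
    s_k <- data$sigma_o[obs]
    ell <- log(data$Y[obs])
    mu <- log(psi_stage[i_k]) + logN[obs] - s_k^2 / 2
    val <- val + sum((ell - mu)^2 / (2 * s_k^2) + log(s_k)) +
      K * log(2 * pi) / 2
    D <- dep_cache %||% obs_dependence(i_k, t_k, n, T)
    # d mu / d u: 1 for recruitment coords, dlog(phi)/dx for survival coords
    if (surv_lognormal) {
      gp <- rep(1, (n - 1L) * T)
      gpp <- rep(0, (n - 1L) * T)
    } else {
      x <- u[-seq_len(T)]
      p <- invlogit(x)
      gp <- 1 - p          # d log phi / d logit phi
      gpp <- -p * (1 - p)
    }
    scale <- c(rep(1, T), gp)
    A <- sweep(D, 2, scale, "*")
    e <- (mu - ell) / s_k^2
    g <- g + drop(crossprod(A, e))
    W <- 1 / s_k^2
    H <- crossprod(A * sqrt(W)) + diag(H_diag, length(u))
    curve_extra <- c(rep(0, T), gpp) * drop(crossprod(D, e))
    diag(H) <- diag(H) + curve_extra
  } else {
    H <- diag(H_diag, length(u))
  }
  # Y_init depends only on parameters; add its value contribution
  if (!is.na(data$Y_init)) {
    mu0 <- unname(log(psi_stage[n])) + params$log_N_init -
      data$sigma_o_init^2 / 2
    val <- val + (log(data$Y_init) - mu0)^2 / (2 * data$sigma_o_init^2) +
      log(data$sigma_o_init) + log(2 * pi) / 2
  }
  list(value = val, gradient = g, hessian = H)
}

#' Mode of the latent states given parameters and data
#'
#' Minimizes the joint negative log-density over the latent vital-rate block
#' by Newton's method with backtracking line search, using analytic gradients
#' and Hessians. This is the inner optimization of the Laplace approximation.
#'
#' @param params A [lifecycle_params()].
#' @param data An [ssm_dataset()].
#' @param u0 Optional starting [latent_states()] (defaults to the process
#'   means).
#' @param tol Convergence tolerance on the max-norm of the gradient.
#' @param max_iter Maximum Newton iterations.
#' @param surv_lognormal Use the linear-Gaussian (log-normal survival) test
#'   variant of the model.
#' @return A list with `latent` (the mode), `hessian` of the joint negative
#'   log-density at the mode, `value`, `grad_norm`, `converged` and
#'   `iterations`.
#' @export
inner_mode <- function(params, data, u0 = NULL, tol = 1e-8, max_iter = 200L,
                       surv_lognormal = FALSE) {
  n <- params$n_stages
  T <- data$T
  u <- if (is.null(u0)) process_moments(params, data$covariates)$mean
       else pack_latent(u0)
  d <- joint_nll_u_deriv(params, u, data, surv_lognormal)
  iter <- 0L
  while (max(abs(d$gradient)) > tol && iter < max_iter) {
    iter <- iter + 1L
    step <- newton_step(d$hessian, d$gradient)
    alpha <- 1
    repeat {
      u_new <- u + alpha * step
      d_new <- tryCatch(joint_nll_u_deriv(params, u_new, data, surv_lognormal),
                        error = function(e) NULL)
      if (!is.null(d_new) && is.finite(d_new$value) &&
          d_new$value <= d$value + 1e-12 * abs(d$value)) break
      alpha <- alpha / 2
      if (alpha < 1e-12) break
    }
    if (alpha < 1e-12) break
    u <- u_new
    d <- d_new
  }
  gn <- max(abs(d$gradient))
  list(latent = unpack_latent(u, n, T), hessian = d$hessian, value = d$value,
       grad_norm = gn, converged = gn <= tol, iterations = iter)
}

# Solve H s = -g, adding a ridge if the Hessian is not positive definite.
newton_step <- function(H, g) {
  lambda <- 0
  for (k in 0:12) {
    ch <- tryCatch(chol(H + diag(lambda, nrow(H))), error = function(e) NULL)
    if (!is.null(ch)) return(-backsolve(ch, forwardsolve(t(ch), g)))
    lambda <- if (lambda == 0) 1e-8 * max(1, max(abs(diag(H)))) else 10 * lambda
  }
  -g / max(abs(diag(H)))  # steepest descent fallback
}

#' Laplace-approximated negative marginal log-likelihood
#'
#' Integrates the latent vital rates out of the joint density by the Laplace
#' approximation: the joint negative log-density at the latent mode, plus
#' half the log-determinant of its Hessian there, minus `dim(u)/2 * log(2*pi)`.
#'
#' @inheritParams inner_mode
#' @return A scalar; attributes carry the inner mode and convergence flag.
#' @export
marginal_nll <- function(params, data, u0 = NULL, surv_lognormal = FALSE) {
  im <- inner_mode(params, data, u0, surv_lognormal = surv_lognormal)
  if (!im$converged)
    warning("inner optimization did not reach gradient tolerance (|g| = ",
            format(im$grad_norm), ")")
  ch <- tryCatch(chol(im$hessian), error = function(e) NULL)
  if (is.null(ch)) {
    ev <- eigen(im$hessian, symmetric = TRUE, only.values = TRUE)$values
    stop("joint Hessian not positive definite at the latent mode ",
         "(smallest eigenvalue ", format(min(ev)), ")")
  }
  d <- nrow(im$hessian)
  out <- im$value + sum(log(diag(ch))) - d / 2 * log(2 * pi)
  attr(out, "inner") <- im
  out
}
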