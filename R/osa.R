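# One-step-ahead prediction residuals via the Gaussian (Laplace) filtering
# approximation: each observation is standardized against the predictive
# distribution of its log-index given all earlier observations at the fitted
# parameters. Under a correctly specified model the residuals are
# approximately i.i.d. standard normal.

# Newton solve of the latent mode using only the observations flagged in
# obs_mask (a logical n x T matrix); prior-only when nothing is observed.
inner_mode_masked <- function(params, data, obs_mask, u0 = NULL,
                              tol = 1e-8, max_iter = 200L) {
  u <- u0 %||% process_moments(params, data$covariates)$mean
  d <- joint_nll_u_deriv(params, u, data, obs_mask = obs_mask)
  iter <- 0L
  while (max(abs(d$gradient)) > tol && iter < max_iter) {
    iter <- iter + 1L
    step <- newton_step(d$hessian, d$gradient)
    alpha <- 1
    repeat {
      d_new <- tryCatch(
        joint_nll_u_deriv(params, u + alpha * step, data,
                          obs_mask = obs_mask),
        error = function(e) NULL)
      if (!is.null(d_new) && is.finite(d_new$value) &&
          d_new$value <= d$value + 1e-12 * abs(d$value)) break
      alpha <- alpha / 2
      if (alpha < 1e-12) break
    }
    if (alpha < 1e-12) break
    u <- u + alpha * step
    d <- d_new
  }
  list(u = u, hessian = d$hessian)
}

#' One-step-ahead prediction residuals
#'
#' For each observation in time order (the initial adult index first, then
#' cohort by cohort, stage by stage), computes the Laplace-Gaussian
#' predictive distribution of its log-index given all earlier observations
#' at the fitted parameters, and standardizes the observed log-index against
#' it. The predictive variance combines the known observation variance with
#' the propagated latent-state uncertainty.
#'
#' @param fit An [fit_mle()] result.
#' @param data Dataset to compute residuals for (defaults to the fitted
#'   data).
#' @return A data.frame with columns `stage`, `cohort` (0 for the initial
#'   adult index), `residual`, `mu_pred` and `sd_pred`, in prediction order.
#'   Missing observations are skipped.
#' @export
osa_residuals <- function(fit, data = fit$data) {
  params <- fit$theta_hat
  n <- params$n_stages
  T <- data$T
  psi_stage <- params$psi[data$survey_of_stage]
  out <- list()
  if (!is.na(data$Y_init)) {
    mu0 <- log(psi_stage[n]) + params$log_N_init - data$sigma_o_init^2 / 2
    out[[1]] <- data.frame(stage = n, cohort = 0L,
                           residual = (log(data$Y_init) - mu0) /
                             data$sigma_o_init,
                           mu_pred = mu0, sd_pred = data$sigma_o_init)
  }
  obs <- !is.na(data$Y)
  ord <- which(obs, arr.ind = TRUE)
  ord <- ord[order(ord[, 2], ord[, 1]), , drop = FALSE]
  mask <- matrix(FALSE, n, T)
  u <- process_moments(params, data$covariates)$mean
  for (k in seq_len(nrow(ord))) {
    i <- ord[k, 1]; t <- ord[k, 2]
    im <- inner_mode_masked(params, data, mask, u0 = u)
    u <- im$u
    # predictive mean and design row of this observation at the mode
    latent <- unpack_latent(u, n, T)
    logN <- log_abundances(params$log_N_init, latent$log_rho,
                           latent$logit_phi)
    s <- data$sigma_o[i, t]
    mu <- log(psi_stage[i]) + logN[i, t] - s^2 / 2
    D <- obs_dependence(i, t, n, T)
    p <- invlogit(u[-seq_len(T)])
    a <- drop(D) * c(rep(1, T), 1 - p)
    v <- s^2 + drop(crossprod(a, solve(im$hessian, a)))
    out[[length(out) + 1L]] <- data.frame(
      stage = i, cohort = t, residual = (log(data$Y[i, t]) - mu) / sqrt(v),
      mu_pred = mu, sd_pred = sqrt(v))
    mask[i, t] <- TRUE
  }
  do.call(rbind, out)
}
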