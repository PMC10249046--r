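# TMB-backed maximum-likelihood fitting of the life-cycle SSM. The latent
# vital rates are integrated out by the Laplace approximation; free
# parameters are optimized on unconstrained scales (log sigma, log psi,
# log N, beta as-is).

# Coordinate names of the fixed-effect blocks, in TMB parameter order.
coord_names <- function(data) {
  n <- data$n_stages
  sv <- surveys_of(data)
  mR <- ncol(data$covariates$w_R) - 1L
  mS <- vapply(data$covariates$w_S, ncol, 1L) - 1L
  list(
    log_N_init = "log_N_init",
    beta_R = paste0("beta_R_", 0:mR),
    beta_S = unlist(lapply(seq_len(n - 1L),
                           function(i) paste0("beta_S", i, "_", 0:mS[i]))),
    log_sigma_pR = "log_sigma_p_R",
    log_sigma_pS = paste0("log_sigma_p_S", seq_len(n - 1L)),
    log_psi = paste0("log_psi_", sv)
  )
}

tmb_data_list <- function(data, surv_lognormal = FALSE) {
  obs <- !is.na(data$Y)
  logY <- ifelse(obs, log(data$Y), 0)
  sv <- surveys_of(data)
  wS <- do.call(cbind, data$covariates$w_S)
  wS_len <- vapply(data$covariates$w_S, ncol, 1L)
  list(logY = logY, obs = obs * 1L,
       sigma_o = ifelse(obs, data$sigma_o, 1),
       has_Y_init = as.integer(!is.na(data$Y_init)),
       logY_init = if (is.na(data$Y_init)) 0 else log(data$Y_init),
       sigma_o_init = if (is.na(data$Y_init)) 1 else data$sigma_o_init,
       wR = data$covariates$w_R, wS = wS,
       wS_off = c(0L, cumsum(wS_len))[seq_along(wS_len)],
       wS_len = wS_len,
       psi_index = match(data$survey_of_stage, sv) - 1L,
       surv_lognormal = as.integer(surv_lognormal))
}

tmb_par_list <- function(params, data, latent = NULL) {
  sv <- surveys_of(data)
  latent <- latent %||%
    unpack_latent(process_moments(params, data$covariates)$mean,
                  params$n_stages, data$T)
  list(log_N_init = params$log_N_init,
       beta_R = params$beta_R,
       beta_S = unlist(params$beta_S),
       log_sigma_pR = log(params$sigma_p_R),
       log_sigma_pS = log(params$sigma_p_S),
       log_psi = log(unname(params$psi[sv])),
       log_rho = latent$log_rho,
       logit_phi = latent$logit_phi)
}

# Build TMB map factors fixing the requested coordinates, and return the
# adjusted start values alongside.
tmb_map_and_start <- function(pars, cn, fix_psi, fix_log_N_init, fix_coords,
                              sv) {
  fixed <- logical(0)
  for (b in names(cn)) fixed[cn[[b]]] <- FALSE
  vals <- stats::setNames(numeric(0), character(0))
  if (length(fix_psi)) {
    bad <- setdiff(names(fix_psi), sv)
    if (length(bad)) stop("fix_psi names unknown surveys: ",
                          paste(bad, collapse = ", "))
    vals[paste0("log_psi_", names(fix_psi))] <- log(fix_psi)
  }
  if (!is.null(fix_log_N_init)) vals["log_N_init"] <- fix_log_N_init
  if (length(fix_coords)) {
    bad <- setdiff(names(fix_coords), unlist(cn))
    if (length(bad)) stop("unknown parameter coordinates: ",
                          paste(bad, collapse = ", "))
    vals[names(fix_coords)] <- fix_coords
  }
  fixed[names(vals)] <- TRUE
  map <- list()
  for (b in names(cn)) {
    f <- fixed[cn[[b]]]
    if (any(f)) {
      fac <- seq_along(cn[[b]])
      fac[f] <- NA
      map[[b]] <- factor(fac)
      pars[[b]][f] <- vals[cn[[b]][f]]
    }
  }
  list(map = map, pars = pars,
       free_names = unlist(cn, use.names = FALSE)[!fixed[unlist(cn)]])
}

# Crude latent states implied by the indices at given biases: back out
# abundances, fill gaps by interpolation, infer vital rates by differencing.
crude_states <- function(data, psi) {
  n <- data$n_stages
  T <- data$T
  psi_stage <- psi[match(data$survey_of_stage, names(psi))]
  logN <- log(data$Y) - log(psi_stage)   # recycled by row
  for (i in seq_len(n)) {                # fill gaps within stage
    y <- logN[i, ]
    if (all(is.na(y))) y <- rep(mean(logN, na.rm = TRUE), T)
    else if (anyNA(y)) y <- stats::approx(seq_len(T), y, seq_len(T),
                                          rule = 2)$y
    logN[i, ] <- y
  }
  log_N_init <- if (!is.na(data$Y_init))
    log(data$Y_init) - log(psi_stage[n])
  else logN[n, 1]
  adult_prev <- c(log_N_init, logN[n, -T])
  log_rho <- logN[1, ] - adult_prev
  logit_phi <- matrix(0, n - 1L, T)
  for (i in seq_len(n - 1L)) {
    phi <- pmin(pmax(exp(logN[i + 1L, ] - logN[i, ]), 0.02), 0.98)
    logit_phi[i, ] <- log(phi / (1 - phi))
  }
  list(logN = logN, log_N_init = log_N_init, log_rho = log_rho,
       logit_phi = logit_phi)
}

# Crude data-driven starting values: crude latent states, then moment-match
# the regression intercepts and process SDs.
start_params <- function(data, fix_psi = NULL) {
  n <- data$n_stages
  sv <- surveys_of(data)
  psi <- stats::setNames(rep(1, length(sv)), sv)
  if (length(fix_psi)) psi[names(fix_psi)] <- fix_psi
  cs <- crude_states(data, psi)
  beta0 <- function(x, k) c(mean(x), rep(0, k - 1L))
  lifecycle_params(
    n_stages = n,
    log_N_init = cs$log_N_init,
    beta_R = beta0(cs$log_rho, ncol(data$covariates$w_R)),
    beta_S = lapply(seq_len(n - 1L), function(i)
      beta0(cs$logit_phi[i, ], ncol(data$covariates$w_S[[i]]))),
    sigma_p_R = max(safe_sd(cs$log_rho), 0.15),
    sigma_p_S = pmax(apply(cs$logit_phi, 1, safe_sd), 0.15),
    psi = psi
  )
}

#' Fit the life-cycle SSM by Laplace-approximated maximum likelihood
#'
#' Maximizes the marginal likelihood (latent vital rates integrated out by
#' the Laplace approximation) over the free parameters. The model is
#' identifiable only if at least one bias parameter, or the initial
#' abundance, is held fixed; fits violating this are refused.
#'
#' @param data An [ssm_dataset()].
#' @param fix_psi Named numeric vector of bias parameters to fix, named by
#'   survey label (e.g. `c(S4 = 1)` fixes the stage-4 survey's bias at 1).
#'   All other bias parameters are estimated.
#' @param fix_log_N_init Optional fixed value for `log N[n,0]` (an
#'   alternative identifiability anchor).
#' @param start Optional [lifecycle_params()] starting values; defaults to a
#'   crude moment-matching start derived from the data.
#' @param fix_coords Named numeric vector fixing further individual
#'   coordinates on the optimization scale (names as in the fit's
#'   `free_names`, e.g. `"beta_R_0"`, `"log_sigma_p_S1"`); used internally by
#'   [profile.ssm_fit()] and the grid scan.
#' @param surv_lognormal Fit the linear-Gaussian (log-normal survival) test
#'   variant instead of the logit-normal production model.
#' @param control Passed to [stats::nlminb()]'s `control`.
#' @param light If `TRUE`, skip the delta-method standard-error machinery:
#'   the outer Hessian is still computed for the positive-definiteness flag
#'   and `vcov` is its inverse when available. Used by the replicate
#'   studies, which need point estimates and the flag only.
#' @return An object of class `"ssm_fit"`: parameter estimates
#'   (`theta_hat`), free-parameter vector and covariance (`par`, `vcov`),
#'   maximized marginal log-likelihood (`loglik`), `converged` and
#'   `hessian_pd` flags (reported separately: an optimizer can report
#'   success while the outer Hessian is not positive definite), observation
#'   count and the latent mode.
#' @export
fit_mle <- function(data, fix_psi = NULL, fix_log_N_init = NULL,
                    start = NULL, fix_coords = NULL, surv_lognormal = FALSE,
                    control = list(), light = FALSE) {
  stopifnot(inherits(data, "ssm_dataset"))
  anchored <- length(fix_psi) > 0 || !is.null(fix_log_N_init) ||
    any(grepl("^log_psi_|^log_N_init$", names(fix_coords)))
  if (!anchored)
    stop("model is not identifiable: the initial abundance and the bias ",
         "parameters enter the likelihood only through their products; ",
         "fix at least one psi (fix_psi) or log N[n,0] (fix_log_N_init)")
  start <- start %||% start_params(data, fix_psi)
  check_psi_surveys(start, data)
  cn <- coord_names(data)
  ms <- tmb_map_and_start(tmb_par_list(start, data), cn, fix_psi,
                          fix_log_N_init, fix_coords, surveys_of(data))
  obj <- TMB::MakeADFun(data = tmb_data_list(data, surv_lognormal),
                        parameters = ms$pars, map = ms$map,
                        random = c("log_rho", "logit_phi"),
                        DLL = "stagebias", silent = TRUE)
  finish_fit(obj, ms$free_names, data, fix_psi, fix_log_N_init,
             fix_coords, surv_lognormal, control, light = light)
}

# Optimize an assembled TMB objective and package the result.
finish_fit <- function(obj, free_names, data, fix_psi, fix_log_N_init,
                       fix_coords, surv_lognormal, control = list(),
                       start_vec = NULL, light = FALSE) {
  ctrl <- utils::modifyList(list(iter.max = 1000L, eval.max = 2000L,
                                 rel.tol = 1e-8), control)
  start_vec <- start_vec %||% obj$par
  opt <- if (length(start_vec) == 0L) {
    # fully constrained model: only the latent inner problem is solved
    list(par = start_vec, objective = obj$fn(start_vec), convergence = 0L)
  } else withCallingHandlers(
    stats::nlminb(start_vec, obj$fn, obj$gr, control = ctrl),
    warning = function(w) {
      # transient non-finite trial points are routine for the optimizer
      if (grepl("NA/NaN function evaluation", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  hessian_pd <- length(free_names) == 0L
  vcov <- NULL
  if (length(free_names)) {
    if (light) {
      he <- tryCatch(suppressWarnings(
        stats::optimHess(opt$par, obj$fn, obj$gr)), error = function(e) NULL)
      ch <- if (is.null(he)) NULL else
        tryCatch(chol(he), error = function(e) NULL)
      hessian_pd <- !is.null(ch)
      if (hessian_pd) {
        vcov <- chol2inv(ch)
        dimnames(vcov) <- list(free_names, free_names)
      }
    } else {
      # sdreport warns (NaN standard errors) when the Hessian is not
      # positive definite; that state is reported via hessian_pd instead
      sdr <- tryCatch(suppressWarnings(
        TMB::sdreport(obj, getReportCovariance = FALSE)),
        error = function(e) NULL)
      hessian_pd <- !is.null(sdr) && isTRUE(sdr$pdHess)
      if (!is.null(sdr)) {
        vcov <- sdr$cov.fixed
        dimnames(vcov) <- list(free_names, free_names)
      }
    }
  }
  pl <- obj$env$parList(opt$par, obj$env$last.par.best)
  theta_hat <- params_from_parlist(pl, data)
  structure(list(
    theta_hat = theta_hat,
    par = stats::setNames(opt$par, free_names),
    free_names = free_names,
    vcov = vcov,
    loglik = -opt$objective,
    converged = opt$convergence == 0L,
    hessian_pd = hessian_pd,
    n_obs = n_obs(data),
    latent_mode = latent_states(pl$log_rho, pl$logit_phi),
    fix_psi = fix_psi, fix_log_N_init = fix_log_N_init,
    fix_coords = fix_coords, surv_lognormal = surv_lognormal,
    data = data, obj = obj, opt = opt
  ), class = "ssm_fit")
}

# Free-coordinate start vector in the objective's parameter order.
free_start_vec <- function(ms, cn) {
  out <- numeric(0)
  for (b in names(cn)) {
    v <- ms$pars[[b]]
    if (!is.null(ms$map[[b]])) v <- v[!is.na(ms$map[[b]])]
    out <- c(out, v)
  }
  out
}

# Re-fit an existing objective on a fresh dataset with identical
# dimensions and missingness pattern: the data are updated in place (the
# compiled template declares them updatable), skipping tape construction.
# The inner (latent) state is reset to the new start's process means so the
# warm tape does not mislead the inner optimizer.
refit_with <- function(fit0, data, fix_psi, start = NULL, control = list(),
                       light = TRUE) {
  obj <- fit0$obj
  stopifnot(identical(dim(data$Y), dim(fit0$data$Y)),
            identical(is.na(data$Y), is.na(fit0$data$Y)))
  obs <- !is.na(data$Y)
  obj$env$data$logY <- ifelse(obs, log(data$Y), 0)
  obj$env$data$wR <- data$covariates$w_R
  obj$env$data$wS <- do.call(cbind, data$covariates$w_S)
  obj$env$data$logY_init <- if (is.na(data$Y_init)) 0 else log(data$Y_init)
  start <- start %||% start_params(data, fix_psi)
  cn <- coord_names(data)
  ms <- tmb_map_and_start(tmb_par_list(start, data), cn, fix_psi,
                          fit0$fix_log_N_init, fit0$fix_coords,
                          surveys_of(data))
  u0 <- process_moments(start, data$covariates)$mean
  obj$env$last.par[obj$env$random] <- u0
  obj$env$last.par.best[obj$env$random] <- u0
  finish_fit(obj, ms$free_names, data, fix_psi, fit0$fix_log_N_init,
             fit0$fix_coords, fit0$surv_lognormal, control,
             start_vec = free_start_vec(ms, cn), light = light)
}

params_from_parlist <- function(pl, data) {
  n <- data$n_stages
  sv <- surveys_of(data)
  wS_len <- vapply(data$covariates$w_S, ncol, 1L)
  off <- c(0L, cumsum(wS_len))
  beta_S <- lapply(seq_len(n - 1L),
                   function(i) pl$beta_S[(off[i] + 1L):off[i + 1L]])
  psi <- stats::setNames(exp(pl$log_psi), sv)
  lifecycle_params(n_stages = n, log_N_init = pl$log_N_init,
                   beta_R = pl$beta_R, beta_S = beta_S,
                   sigma_p_R = exp(pl$log_sigma_pR),
                   sigma_p_S = exp(pl$log_sigma_pS),
                   psi = psi)
}

#' @export
print.ssm_fit <- function(x, ...) {
  cat("Life-cycle SSM fit (Laplace ML)\n")
  cat(sprintf("  log-likelihood %.4f | %d free parameters | %d observations\n",
              x$loglik, length(x$par), x$n_obs))
  cat(sprintf("  converged: %s | Hessian positive definite: %s\n",
              x$converged, x$hessian_pd))
  print(summary_table(x), digits = 4)
  invisible(x)
}

summary_table <- function(fit) {
  se <- if (!is.null(fit$vcov)) sqrt(pmax(diag(fit$vcov), 0)) else
    rep(NA_real_, length(fit$par))
  data.frame(parameter = fit$free_names, estimate = unname(fit$par),
             se = unname(se), row.names = NULL)
}

#' @export
logLik.ssm_fit <- function(object, ...) {
  structure(object$loglik, df = length(object$par),
            nobs = object$n_obs, class = "logLik")
}

#' Small-sample corrected Akaike information criterion
#'
#' `AICc = -2 loglik + 2k + 2k(k + 1) / (n - k - 1)` with `k` the number of
#' free parameters and `n` the number of non-missing index observations
#' (including the initial adult index when present).
#'
#' @param fit An [fit_mle()] result.
#' @return A scalar.
#' @export
aicc <- function(fit) {
  k <- length(fit$par)
  n <- fit$n_obs
  if (n <= k + 1L)
    stop("AICc undefined: n_obs (", n, ") must exceed k + 1 (", k + 1L, ")")
  -2 * fit$loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Likelihood-ratio test between nested fits
#'
#' The statistic is twice the difference in maximized (marginal)
#' log-likelihoods, referred to a chi-square distribution with degrees of
#' freedom equal to the difference in free-parameter counts.
#'
#' @param fit_nested,fit_full Either [fit_mle()] results or bare maximized
#'   log-likelihood values.
#' @param df Degrees of freedom; required when bare log-likelihoods are
#'   given, otherwise inferred from the free-parameter sets (which must
#'   nest).
#' @return An object of class `"htest"` with `statistic`, `parameter` (df)
#'   and `p.value`.
#' @export
lrt <- function(fit_nested, fit_full, df = NULL) {
  ll <- function(x) if (inherits(x, "ssm_fit")) x$loglik else as.numeric(x)
  if (is.null(df)) {
    if (!inherits(fit_nested, "ssm_fit") || !inherits(fit_full, "ssm_fit"))
      stop("df must be given when bare log-likelihoods are supplied")
    if (!all(fit_nested$free_names %in% fit_full$free_names))
      stop("models are not nested: the nested fit's free parameters must be ",
           "a subset of the full fit's")
    df <- length(fit_full$par) - length(fit_nested$par)
  }
  stat <- 2 * (ll(fit_full) - ll(fit_nested))
  if (stat < -1e-6)
    warning("full model has lower log-likelihood than nested model; ",
            "this usually indicates an optimizer failure")
  p <- stats::pchisq(max(stat, 0), df, lower.tail = FALSE)
  structure(list(statistic = c(X2 = stat), parameter = c(df = df),
                 p.value = p,
                 method = "Likelihood-ratio test (marginal likelihoods)",
                 data.name = "nested vs. full model"),
            class = "htest")
}

#' Profile likelihood over one or more parameters
#'
#' At each grid point the named parameter coordinates are held fixed and the
#' model is re-optimized in all remaining free parameters, warm-started from
#' the nearest already-computed point (proceeding outward from the MLE for
#' one-dimensional grids).
#'
#' @param fitted An [fit_mle()] result.
#' @param params Character vector of free-parameter coordinate names (on the
#'   optimization scale, e.g. `"beta_R_0"` or `"log_psi_S2"`).
#' @param grid For one parameter, a numeric vector of values; in general a
#'   data.frame with one column per profiled parameter.
#' @param ... Passed to [fit_mle()].
#' @return A data.frame of class `"ssm_profile"`: the grid, the profile
#'   log-likelihood `loglik`, and per-point convergence flags, with the
#'   unconstrained log-likelihood as attribute `"mle_loglik"`.
#' @export
profile.ssm_fit <- function(fitted, params, grid, ...) {
  if (is.numeric(grid) && length(params) == 1L)
    grid <- stats::setNames(data.frame(grid), params)
  grid <- as.data.frame(grid)
  if (!identical(sort(names(grid)), sort(params)))
    stop("grid columns must match the profiled parameter names")
  if (!all(params %in% fitted$free_names))
    stop("can only profile free parameters of the fit; unknown: ",
         paste(setdiff(params, fitted$free_names), collapse = ", "))
  # visit points in order of distance from the MLE so warm starts help
  mle_pt <- fitted$par[params]
  dist <- sqrt(colSums((t(as.matrix(grid[params])) - mle_pt)^2))
  ord <- order(dist)
  out <- grid
  out$loglik <- NA_real_
  out$converged <- NA
  warm <- list()  # start params keyed by visited row, nearest reused
  done <- integer(0)
  for (r in ord) {
    start <- fitted$theta_hat
    if (length(done)) {
      d2 <- sqrt(colSums((t(as.matrix(grid[done, params, drop = FALSE])) -
                            unlist(grid[r, params]))^2))
      start <- warm[[as.character(done[which.min(d2)])]] %||% start
    }
    fc <- c(fitted$fix_coords,
            stats::setNames(as.numeric(grid[r, params]), params))
    f <- tryCatch(
      fit_mle(fitted$data, fix_psi = fitted$fix_psi,
              fix_log_N_init = fitted$fix_log_N_init, start = start,
              fix_coords = fc, surv_lognormal = fitted$surv_lognormal, ...),
      error = function(e) NULL)
    if (!is.null(f)) {
      out$loglik[r] <- f$loglik
      out$converged[r] <- f$converged
      warm[[as.character(r)]] <- f$theta_hat
    } else out$converged[r] <- FALSE
    done <- c(done, r)
  }
  structure(out, mle_loglik = fitted$loglik, params = params,
            class = c("ssm_profile", "data.frame"))
}
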