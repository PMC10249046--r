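# Bayesian fitting of the life-cycle SSM: adaptive random-walk
# Metropolis-within-Gibbs over the free parameters (natural scale) and the
# latent vital rates (one block per cohort), with proposal scales adapted
# during burn-in only so the post-burn-in kernel is a fixed, valid MCMC.

#' Default priors for the life-cycle SSM parameters
#'
#' Initial log-abundance: Uniform(9, 15). Recruitment coefficients:
#' Normal(0, tau = 1). Survival coefficients: Normal(0, tau = 3(m+1)/pi^2)
#' with `m` the number of covariates of that vital rate (0.61 at m = 1).
#' Process SDs and bias parameters: Exponential(1). Priors are specified by
#' precision `tau = 1/sigma^2` for the normal family.
#'
#' @param data An [ssm_dataset()].
#' @return A named list of prior descriptors, one per model parameter
#'   (including every bias parameter; which are sampled is decided by the
#'   fix specification at sampling time).
#' @export
default_priors <- function(data) {
  n <- data$n_stages
  sv <- surveys_of(data)
  pr <- list(log_N_init = list(family = "uniform", lower = 9, upper = 15))
  mR <- ncol(data$covariates$w_R) - 1L
  for (j in 0:mR)
    pr[[paste0("beta_R_", j)]] <- list(family = "normal", mean = 0, prec = 1)
  for (i in seq_len(n - 1L)) {
    m <- ncol(data$covariates$w_S[[i]]) - 1L
    tau <- 3 * (m + 1) / pi^2
    for (j in 0:m)
      pr[[paste0("beta_S", i, "_", j)]] <-
        list(family = "normal", mean = 0, prec = tau)
  }
  pr$sigma_p_R <- list(family = "exponential", rate = 1)
  for (i in seq_len(n - 1L))
    pr[[paste0("sigma_p_S", i)]] <- list(family = "exponential", rate = 1)
  for (s in sv)
    pr[[paste0("psi_", s)]] <- list(family = "exponential", rate = 1)
  pr
}

prior_logpdf_1 <- function(p, x) {
  if (!is.finite(x)) return(-Inf)
  switch(p$family,
         uniform = if (x >= p$lower && x <= p$upper)
           -log(p$upper - p$lower) else -Inf,
         normal = stats::dnorm(x, p$mean, 1 / sqrt(p$prec), log = TRUE),
         exponential = if (x > 0) stats::dexp(x, p$rate, log = TRUE) else -Inf,
         stop("unknown prior family: ", p$family))
}

set_param_value <- function(params, name, value) {
  if (name == "log_N_init") params$log_N_init <- value
  else if (name == "sigma_p_R") params$sigma_p_R <- value
  else if (grepl("^sigma_p_S", name))
    params$sigma_p_S[as.integer(sub("^sigma_p_S", "", name))] <- value
  else if (grepl("^beta_R_", name))
    params$beta_R[as.integer(sub("^beta_R_", "", name)) + 1L] <- value
  else if (grepl("^beta_S", name)) {
    m <- regmatches(name, regexec("^beta_S([0-9]+)_([0-9]+)$", name))[[1]]
    params$beta_S[[as.integer(m[2])]][as.integer(m[3]) + 1L] <- value
  } else if (grepl("^psi_", name))
    params$psi[sub("^psi_", "", name)] <- value
  else stop("unknown parameter name: ", name)
  params
}

# Natural-scale value of a named parameter coordinate.
param_value <- function(params, name) {
  if (name == "log_N_init") return(params$log_N_init)
  if (name == "sigma_p_R") return(params$sigma_p_R)
  m <- regmatches(name, regexec("^sigma_p_S([0-9]+)$", name))[[1]]
  if (length(m)) return(params$sigma_p_S[as.integer(m[2])])
  m <- regmatches(name, regexec("^beta_R_([0-9]+)$", name))[[1]]
  if (length(m)) return(params$beta_R[as.integer(m[2]) + 1L])
  m <- regmatches(name, regexec("^beta_S([0-9]+)_([0-9]+)$", name))[[1]]
  if (length(m)) return(params$beta_S[[as.integer(m[2])]][as.integer(m[3]) + 1L])
  m <- regmatches(name, regexec("^psi_(.+)$", name))[[1]]
  if (length(m)) return(unname(params$psi[m[2]]))
  stop("unknown parameter name: ", name)
}

#' Log prior density of a parameter set
#'
#' Sums the log prior densities of the requested (free) parameters;
#' `-Inf` outside any prior's support.
#'
#' @param params A [lifecycle_params()].
#' @param priors A prior list as from [default_priors()].
#' @param free_names Which parameters to include (default: all in `priors`).
#' @return A scalar.
#' @export
log_prior <- function(params, priors, free_names = names(priors)) {
  sum(vapply(free_names, function(nm) {
    if (is.null(priors[[nm]])) stop("no prior specified for ", nm)
    prior_logpdf_1(priors[[nm]], param_value(params, nm))
  }, 0))
}

#' Sample the posterior by adaptive Metropolis-within-Gibbs
#'
#' Random-walk Metropolis updates of each free parameter (on its natural
#' scale; proposals outside a prior's support are rejected) and of the
#' latent vital rates one cohort-block at a time. Proposal scales adapt
#' toward standard acceptance targets during burn-in and are frozen
#' afterwards. Fully reproducible given `seed`.
#'
#' @param data An [ssm_dataset()].
#' @param priors Prior list (default [default_priors()]).
#' @param fix_psi Named vector of bias parameters held fixed (identifiability
#'   anchor, as in [fit_mle()]).
#' @param fix_log_N_init Optional fixed `log N[n,0]`.
#' @param n_chains,n_iter Number of chains and iterations per chain.
#' @param burn_in Iterations discarded (and used for adaptation); default
#'   half of `n_iter`.
#' @param seed Integer master seed.
#' @param init Optional list of [lifecycle_params()] (one per chain) used as
#'   starting points; by default chains start from an overdispersed jitter
#'   around a crude data-driven estimate.
#' @param fix_params Optional named numeric vector holding further
#'   parameters fixed at given values during sampling (natural-scale names,
#'   e.g. `c(sigma_p_R = 0.5)`); parameters not estimated are fixed this
#'   way.
#' @param likelihood If `FALSE` the observation likelihood is switched off
#'   and the sampler targets the prior-times-process model (used to validate
#'   the sampler against the priors).
#' @param force Set `TRUE` to sample a non-identified model (no psi or
#'   initial-abundance anchor) for redundancy demonstrations.
#' @return An object of class `"chain_set"`: `draws` is an
#'   `(n_iter - burn_in) x n_chains x n_params` array of post-burn-in
#'   parameter draws on natural scales.
#' @export
sample_posterior <- function(data, priors = default_priors(data),
                             fix_psi = NULL, fix_log_N_init = NULL,
                             n_chains = 4L, n_iter = 20000L,
                             burn_in = floor(n_iter / 2), seed = 1L,
                             init = NULL, fix_params = NULL,
                             likelihood = TRUE, force = FALSE) {
  stopifnot(inherits(data, "ssm_dataset"))
  if (!force && length(fix_psi) == 0 && is.null(fix_log_N_init))
    stop("model is not identifiable: fix at least one bias parameter or ",
         "log N[n,0] (or pass force = TRUE for redundancy demonstrations)")
  n <- data$n_stages
  T <- data$T
  sv <- surveys_of(data)
  free <- setdiff(free_param_names(data, fix_psi, fix_log_N_init),
                  names(fix_params))
  n_keep <- n_iter - burn_in
  draws <- array(NA_real_, c(n_keep, n_chains, length(free)),
                 dimnames = list(NULL, NULL, free))
  seeds <- child_seeds(seed, n_chains)
  accept <- vector("list", n_chains)
  prop <- build_proposals(data, free, fix_psi, fix_log_N_init, likelihood)
  prop_L <- prop$grand
  indep <- prop$indep
  for (ch in seq_len(n_chains)) {
    res <- with_seed(seeds[ch], {
      start <- if (!is.null(init)) init[[ch]]
               else jitter_start(data, fix_psi, fix_log_N_init)
      for (nm in names(fix_params))
        start <- set_param_value(start, nm, fix_params[[nm]])
      run_chain(data, priors, start, free, fix_psi, fix_log_N_init,
                n_iter, burn_in, likelihood, prop_L, indep)
    })
    draws[, ch, ] <- res$draws
    accept[[ch]] <- res$accept
  }
  structure(list(draws = draws, params = free, n_chains = n_chains,
                 n_iter = n_iter, burn_in = burn_in, seed = seed,
                 acceptance = accept),
            class = "chain_set")
}

# Frozen proposal machinery built once from a Laplace ML fit, on link
# scales (log for SDs and biases): the Cholesky factor of the correlated
# ("grand") random-walk covariance, and the center/scale of the
# heavy-tailed independence proposal. Both follow the posterior's
# correlation ridges; a diagonal fallback applies when the fit is
# unavailable. Frozen for the whole run, so the kernel stays fixed.
build_proposals <- function(data, free, fix_psi, fix_log_N_init,
                            likelihood) {
  link_of <- function(nm) {
    ifelse(grepl("^sigma_p_S", nm), sub("^sigma_p_", "log_sigma_p_", nm),
    ifelse(nm == "sigma_p_R", "log_sigma_p_R",
    ifelse(grepl("^psi_", nm), sub("^psi_", "log_psi_", nm), nm)))
  }
  d <- length(free)
  Sigma <- diag(0.05^2, d)
  dimnames(Sigma) <- list(free, free)
  indep <- NULL
  if (likelihood) {
    fit <- tryCatch(
      suppressWarnings(fit_mle(data, fix_psi = fix_psi,
                               fix_log_N_init = fix_log_N_init)),
      error = function(e) NULL)
    if (!is.null(fit) && fit$hessian_pd && !is.null(fit$vcov) &&
        all(is.finite(fit$vcov))) {
      ln <- link_of(free)
      hit <- ln %in% rownames(fit$vcov)
      Sigma[hit, hit] <- fit$vcov[ln[hit], ln[hit]]
      if (all(hit)) {
        S_ind <- Sigma * 1.2^2 + diag(1e-10, d)
        Ls <- tryCatch(chol(S_ind), error = function(e) NULL)
        if (!is.null(Ls))
          indep <- list(m = unname(fit$par[ln]), L = Ls,
                        logdet = 2 * sum(log(diag(Ls))), df = 6)
      }
    }
  }
  ch <- tryCatch(chol(Sigma), error = function(e) NULL)
  if (is.null(ch))
    ch <- chol(Sigma + diag(1e-8 + abs(min(eigen(Sigma)$values)), d))
  list(grand = ch, indep = indep)
}

free_param_names <- function(data, fix_psi, fix_log_N_init) {
  n <- data$n_stages
  sv <- surveys_of(data)
  nm <- c(if (is.null(fix_log_N_init)) "log_N_init",
          paste0("beta_R_", 0:(ncol(data$covariates$w_R) - 1L)),
          unlist(lapply(seq_len(n - 1L), function(i)
            paste0("beta_S", i, "_",
                   0:(ncol(data$covariates$w_S[[i]]) - 1L)))),
          "sigma_p_R", paste0("sigma_p_S", seq_len(n - 1L)),
          if (length(setdiff(sv, names(fix_psi))))
            paste0("psi_", setdiff(sv, names(fix_psi))))
  nm
}

jitter_start <- function(data, fix_psi, fix_log_N_init) {
  p <- start_params(data, fix_psi)
  p$beta_R <- p$beta_R + stats::rnorm(length(p$beta_R), 0, 0.5)
  p$beta_S <- lapply(p$beta_S, function(b) b + stats::rnorm(length(b), 0, 0.5))
  p$sigma_p_R <- p$sigma_p_R * exp(stats::rnorm(1, 0, 0.3))
  p$sigma_p_S <- p$sigma_p_S * exp(stats::rnorm(length(p$sigma_p_S), 0, 0.3))
  free_psi <- setdiff(names(p$psi), names(fix_psi))
  p$psi[free_psi] <- p$psi[free_psi] * exp(stats::rnorm(length(free_psi), 0, 0.5))
  p$log_N_init <- if (!is.null(fix_log_N_init)) fix_log_N_init
    else min(max(p$log_N_init + stats::rnorm(1, 0, 0.5), 9.05), 14.95)
  p
}

# Single-chain sampler. State lives in a local environment; component
# log-likelihoods are cached and only the parts touched by each update are
# recomputed.
run_chain <- function(data, priors, start, free, fix_psi, fix_log_N_init,
                      n_iter, burn_in, likelihood, prop_L, indep = NULL) {
  n <- data$n_stages
  T <- data$T
  sv <- surveys_of(data)
  obs <- !is.na(data$Y)
  o_lin <- which(obs)
  o_psi <- match(data$survey_of_stage, sv)[which(obs, arr.ind = TRUE)[, 1]]
  o_logy <- log(data$Y[o_lin])
  o_s <- data$sigma_o[o_lin]
  o_half <- o_s^2 / 2
  o_logs_const <- sum(log(o_s)) + length(o_s) * 0.918938533204673
  has0 <- !is.na(data$Y_init)
  psi_idx <- match(data$survey_of_stage, sv)
  LOG2PI2 <- 0.918938533204673

  st <- as.environment(list(
    log_N_init = start$log_N_init, beta_R = start$beta_R,
    beta_S = start$beta_S, sigma_p_R = start$sigma_p_R,
    sigma_p_S = start$sigma_p_S, psi = start$psi[sv]
  ))
  cs <- crude_states(data, st$psi)
  st$log_rho <- cs$log_rho
  st$logit_phi <- cs$logit_phi
  st$muR <- drop(data$covariates$w_R %*% st$beta_R)
  st$muS <- do.call(rbind, lapply(seq_len(n - 1L), function(i)
    drop(data$covariates$w_S[[i]] %*% st$beta_S[[i]])))

  lp_rho <- function() {
    -0.5 * sum(((st$log_rho - st$muR) / st$sigma_p_R)^2) -
      T * (log(st$sigma_p_R) + LOG2PI2)
  }
  lp_phi <- function(i) {
    -0.5 * sum(((st$logit_phi[i, ] - st$muS[i, ]) / st$sigma_p_S[i])^2) -
      T * (log(st$sigma_p_S[i]) + LOG2PI2)
  }
  calc_logN <- function() {
    lp <- -log1p(exp(-st$logit_phi))
    steps <- st$log_rho + .colSums(lp, n - 1L, T)
    log_first <- st$log_rho +
      st$log_N_init + c(0, cumsum(steps))[seq_len(T)]
    out <- matrix(log_first, n, T, byrow = TRUE)
    acc <- 0
    for (i in seq_len(n - 1L)) {
      acc <- acc + lp[i, ]
      out[i + 1L, ] <- out[i + 1L, ] + acc
    }
    out
  }
  w_lik <- 1   # likelihood annealing weight, ramped during early burn-in
  lp_obs <- function() {
    if (!likelihood) return(0)
    lpsi <- log(st$psi)
    mu <- lpsi[o_psi] + st$logN[o_lin] - o_half
    lp <- -0.5 * sum(((o_logy - mu) / o_s)^2) - o_logs_const
    if (has0) {
      s0 <- data$sigma_o_init
      z <- (log(data$Y_init) - (lpsi[psi_idx[n]] + st$log_N_init -
                                  s0^2 / 2)) / s0
      lp <- lp - 0.5 * z^2 - log(s0) - LOG2PI2
    }
    w_lik * lp
  }
  st$logN <- calc_logN()
  comp <- list(rho = lp_rho(),
               phi = vapply(seq_len(n - 1L), lp_phi, 0),
               obs = lp_obs())

  acc_list <- make_accessors(st, free, priors, data$covariates)

  # ridge moves: rescale a free bias parameter (or the initial abundance)
  # jointly with the exactly compensating latent vital rates, so the sampler
  # can traverse the bias/abundance/survival likelihood ridges that
  # componentwise updates cross only by diffusion
  free_psi_sv <- sv[paste0("psi_", sv) %in% free]
  shift_surveys <- if ("log_N_init" %in% free)
    c(NA_character_, free_psi_sv) else free_psi_sv
  n_shift <- length(shift_surveys)
  shift_stages <- lapply(shift_surveys, function(s)
    if (is.na(s)) integer(0) else which(data$survey_of_stage == s))
  # frozen logit-scale sensitivities mean(1/(1 - phi)) per survival
  # transition, from the crude data-implied states: a log-scale shift of
  # phi by delta is approximately a logit shift of c * delta, so the ridge
  # moves translate the matching intercepts by the same amount, keeping
  # process residuals roughly centered. Frozen constants keep the proposal
  # family fixed (and the kernel valid) across the whole run.
  shift_sens <- {
    cs0 <- crude_states(data, stats::setNames(rep(1, length(sv)), sv))
    phi0 <- 1 / (1 + exp(-cs0$logit_phi))
    pmin(rowMeans(1 / (1 - phi0)), 50)
  }
  # orbit descriptors for the slice moves: per free survey, which stages
  # rescale, how each survival transition and the recruitment rates
  # compensate (per unit of log-psi), and which intercepts translate
  orbits <- lapply(seq_along(shift_surveys), function(k) {
    s <- shift_surveys[k]
    if (is.na(s)) return(NULL)
    I <- shift_stages[[k]]
    dlogN <- rep(0, n)
    dlogN[I] <- -1
    dphi <- dlogN[-1L] - dlogN[-n]
    js <- which(dphi != 0)
    # per affected survival transition: free coefficient coordinates and
    # the projection of a latent change onto their design columns (the
    # coefficients translate by this projection, which telescopes, so the
    # move family is a flow and its pushforward is well defined)
    comp <- lapply(js, function(j) {
      W <- data$covariates$w_S[[j]]
      Jb <- which(paste0("beta_S", j, "_", seq_len(ncol(W)) - 1L) %in% free)
      if (!length(Jb)) return(list(Jb = integer(0)))
      Wf <- W[, Jb, drop = FALSE]
      list(Jb = Jb, W = Wf,
           proj = solve(crossprod(Wf), t(Wf)),
           priors = priors[paste0("beta_S", j, "_", Jb - 1L)])
    })
    WR <- data$covariates$w_R
    JbR <- which(paste0("beta_R_", seq_len(ncol(WR)) - 1L) %in% free)
    compR <- if (length(JbR)) {
      Wf <- WR[, JbR, drop = FALSE]
      list(Jb = JbR, W = Wf, proj = solve(crossprod(Wf), t(Wf)),
           priors = priors[paste0("beta_R_", JbR - 1L)])
    } else list(Jb = integer(0))
    list(s = s, I = I, dphi = dphi, js = js, comp = comp, compR = compR,
         drho1 = dlogN[1L], drho2 = dlogN[1L] - dlogN[n],
         n_in_I = n %in% I,
         psi_prior = priors[[paste0("psi_", s)]])
  })

  # sweep moves: translate a vital-rate coefficient together with its whole
  # latent row (keeping the process residuals fixed), and rescale a process
  # SD together with those residuals. These non-centered companions to the
  # scalar updates let the sampler cross the coefficient-latent funnel that
  # forms where the data constrain a vital rate only weakly.
  sweep_moves <- list()
  for (nm in free) {
    a <- acc_list[[nm]]
    if (grepl("^beta_R_", nm))
      sweep_moves[[length(sweep_moves) + 1L]] <-
        list(nm = nm, rate = 0L,
             x = data$covariates$w_R[, as.integer(sub("^beta_R_", "", nm)) + 1L])
    else if (grepl("^beta_S", nm)) {
      m <- regmatches(nm, regexec("^beta_S([0-9]+)_([0-9]+)$", nm))[[1]]
      sweep_moves[[length(sweep_moves) + 1L]] <-
        list(nm = nm, rate = as.integer(m[2]),
             x = data$covariates$w_S[[as.integer(m[2])]][, as.integer(m[3]) + 1L])
    } else if (nm == "sigma_p_R")
      sweep_moves[[length(sweep_moves) + 1L]] <- list(nm = nm, rate = 0L,
                                                      x = NULL)
    else if (grepl("^sigma_p_S", nm))
      sweep_moves[[length(sweep_moves) + 1L]] <-
        list(nm = nm, rate = as.integer(sub("^sigma_p_S", "", nm)), x = NULL)
  }
  n_sweep <- length(sweep_moves)

  # update descriptors: parameter scalars, latent cohort blocks, ridge and
  # sweep moves
  n_free <- length(free)
  n_grand <- 1L   # correlated-jump attempt per sweep, a cheap worker
                  # along likelihood ridges between independence refreshes
  n_shift_rep <- 1L
  n_indep <- 0L   # full-state independence proposals are disabled: the
                  # latent block's anharmonicity makes whole-posterior
                  # teleports unacceptably improbable at this data size
  # exact Gibbs draws: given the latent rates, the regression coefficients
  # of each vital rate have a conjugate Gaussian conditional (normal prior,
  # normal process density), and the initial log-abundance has a Gaussian
  # conditional truncated to its uniform prior's support
  gibbs_beta <- list()
  for (r in 0:(n - 1L)) {
    W <- if (r == 0L) data$covariates$w_R else data$covariates$w_S[[r]]
    nm_r <- if (r == 0L) paste0("beta_R_", seq_len(ncol(W)) - 1L)
            else paste0("beta_S", r, "_", seq_len(ncol(W)) - 1L)
    J <- which(nm_r %in% free)
    if (length(J) == 0L) next
    prs <- priors[nm_r[J]]
    if (!all(vapply(prs, function(p) identical(p$family, "normal"), TRUE)))
      next
    gibbs_beta[[length(gibbs_beta) + 1L]] <-
      list(rate = r, J = J, W = W,
           tau = vapply(prs, function(p) p$prec, 0),
           mu0 = vapply(prs, function(p) p$mean, 0))
  }
  gibbs_n0 <- "log_N_init" %in% free &&
    identical(priors$log_N_init$family, "uniform")
  # coordinates with exact Gibbs draws do not need scalar random walks
  gibbsed <- c(unlist(lapply(gibbs_beta, function(g) {
    W <- g$W
    nm <- if (g$rate == 0L) paste0("beta_R_", g$J - 1L)
          else paste0("beta_S", g$rate, "_", g$J - 1L)
    nm
  })), if (gibbs_n0) "log_N_init")
  par_free <- setdiff(free, gibbsed)
  par_idx <- match(par_free, free)
  n_gb <- length(gibbs_beta)
  n_g0 <- as.integer(gibbs_n0)
  types <- c(rep("par", length(par_idx)), rep("latent", T),
             rep(rep("shift", n_shift), n_shift_rep),
             rep("sweep", n_sweep), rep("grand", n_grand),
             rep("indep", n_indep), rep("gbeta", n_gb), rep("gn0", n_g0))
  blocks <- c(par_idx, seq_len(T),
              rep(seq_len(n_shift), n_shift_rep),
              seq_len(n_sweep), seq_len(n_grand), seq_len(n_indep),
              seq_len(n_gb), seq_len(n_g0))
  scales <- c(rep(0.2, length(par_idx)), rep(0.3, T),
              rep(0.15, n_shift * n_shift_rep),
              rep(0.2, n_sweep), rep(0.8, n_grand), rep(1, n_indep),
              rep(1, n_gb), rep(1, n_g0))
  target <- ifelse(types == "latent", 0.30,
                   ifelse(types %in% c("grand", "shift"), 0.25, 0.44))
  adaptable <- !types %in% c("indep", "gbeta", "gn0", "shift")  # frozen
  if (!is.null(indep)) {
    indep_logq <- function(xi) {
      z <- backsolve(indep$L, xi - indep$m, transpose = TRUE)
      -(indep$df + n_free) / 2 * log1p(sum(z^2) / indep$df) -
        indep$logdet / 2
    }
    # dependence pattern of observation means on latent coordinates is
    # fixed by the missingness pattern; compute once
    oi_all <- which(obs, arr.ind = TRUE)
    dep_D <- obs_dependence(oi_all[, 1], oi_all[, 2], n, T)
    st_params <- function() {
      lifecycle_params(n, st$log_N_init, st$beta_R, st$beta_S,
                       st$sigma_p_R, st$sigma_p_S, st$psi)
    }
    # Laplace fit of the latent block at given parameters: mode (Newton,
    # warm-started), Cholesky of the joint Hessian, and the density of a
    # given latent vector under the resulting Gaussian
    laplace_u <- function(params, u0) {
      u <- u0
      d <- joint_nll_u_deriv(params, u, data, dep_cache = dep_D)
      for (it in 1:50) {
        if (max(abs(d$gradient)) <= 1e-6) break
        step <- newton_step(d$hessian, d$gradient)
        alpha <- 1
        repeat {
          d_new <- tryCatch(
            joint_nll_u_deriv(params, u + alpha * step, data,
                              dep_cache = dep_D),
            error = function(e) NULL)
          if (!is.null(d_new) && is.finite(d_new$value) &&
              d_new$value <= d$value + 1e-12 * abs(d$value)) break
          alpha <- alpha / 2
          if (alpha < 1e-10) return(NULL)
        }
        u <- u + alpha * step
        d <- d_new
      }
      ch <- tryCatch(chol(d$hessian), error = function(e) NULL)
      if (is.null(ch)) return(NULL)
      list(u_hat = u, chol = ch, logdet = 2 * sum(log(diag(ch))),
           value = d$value)
    }
    gauss_logq <- function(lap, u) {
      z <- lap$chol %*% (u - lap$u_hat)
      -sum(z^2) / 2 + lap$logdet / 2 - length(u) * 0.918938533204673
    }
    d_lat <- T + (n - 1L) * T
  }
  grand_sigma <- ifelse(grepl("^sigma_p", free), TRUE, FALSE)
  grand_psi <- grepl("^psi_", free)
  anneal_len <- if (likelihood) floor(burn_in / 2) else 0L
  # empirical covariance adaptation of the grand proposal (burn-in only):
  # the link-scale parameter history replaces the initial Laplace covariance
  # once enough of it exists, capturing the true length of the posterior's
  # confounding ridges. Frozen at the end of burn-in.
  hist_xi <- matrix(NA_real_, burn_in, n_free)
  link_xi <- function() {
    v <- vapply(acc_list, function(a) a$get(), 0)
    v[grand_sigma | grand_psi] <- log(v[grand_sigma | grand_psi])
    v
  }
  acc <- integer(length(blocks))
  tries <- integer(length(blocks))
  batch <- 0L

  n_keep <- n_iter - burn_in
  out <- matrix(NA_real_, n_keep, n_free)

  for (iter in seq_len(n_iter)) {
    if (anneal_len > 0L && iter <= anneal_len + 1L &&
        (iter %% 25L == 1L || iter == anneal_len + 1L)) {
      w_lik <- min(1, (iter - 1) / anneal_len)
      comp$obs <- lp_obs()
    }
    for (b in seq_along(blocks)) {
      tries[b] <- tries[b] + 1L
      if (types[b] == "par") {
        a <- acc_list[[blocks[b]]]
        old <- a$get()
        lp_old <- prior_logpdf_1(a$prior, old)
        prop <- old + scales[b] * stats::rnorm(1)
        lp_new <- prior_logpdf_1(a$prior, prop)
        if (!is.finite(lp_new)) next
        a$set(prop)
        if (a$kind == "rho") {
          new_rho <- lp_rho()
          if (log_accept(lp_new + new_rho - lp_old - comp$rho)) {
            comp$rho <- new_rho; acc[b] <- acc[b] + 1L
          } else a$set(old)
        } else if (a$kind == "phi") {
          i <- a$i
          new_phi <- lp_phi(i)
          if (log_accept(lp_new + new_phi - lp_old - comp$phi[i])) {
            comp$phi[i] <- new_phi; acc[b] <- acc[b] + 1L
          } else a$set(old)
        } else { # obs-only: psi or the initial log-abundance
          logN_old <- st$logN
          if (a$kind == "logN0") st$logN <- st$logN + (prop - old)
          new_obs <- lp_obs()
          if (log_accept(lp_new + new_obs - lp_old - comp$obs)) {
            comp$obs <- new_obs; acc[b] <- acc[b] + 1L
          } else { a$set(old); st$logN <- logN_old }
        }
      } else if (types[b] == "latent") {
        t <- blocks[b]
        old_rho_t <- st$log_rho[t]
        old_phi_t <- st$logit_phi[, t]
        old_logN <- st$logN
        st$log_rho[t] <- old_rho_t + scales[b] * stats::rnorm(1)
        st$logit_phi[, t] <- old_phi_t + scales[b] * stats::rnorm(n - 1L)
        st$logN <- calc_logN()
        new_rho <- lp_rho()
        new_phi <- vapply(seq_len(n - 1L), lp_phi, 0)
        new_obs <- lp_obs()
        if (log_accept(new_rho + sum(new_phi) + new_obs -
                         comp$rho - sum(comp$phi) - comp$obs)) {
          comp$rho <- new_rho; comp$phi <- new_phi; comp$obs <- new_obs
          acc[b] <- acc[b] + 1L
        } else {
          st$log_rho[t] <- old_rho_t
          st$logit_phi[, t] <- old_phi_t
          st$logN <- old_logN
        }
      } else if (types[b] == "shift") { # orbit slice move
        # Slice-sample along the exact rescaling orbit: the bias parameter
        # (or the initial abundance) moves jointly with the latent rates
        # that compensate it, so every point of the orbit fits the
        # observations equally well. The pushforward density along the
        # orbit is the process density plus priors plus the orbit's
        # Jacobian; slice sampling crosses the whole likelihood ridge in
        # one rejection-free draw (group-move invariance).
        k <- blocks[b]
        s <- shift_surveys[k]
        if (is.na(s)) {
          # initial abundance vs first recruitment
          lo <- priors$log_N_init$lower
          hi <- priors$log_N_init$upper
          n0 <- st$log_N_init
          r1 <- st$log_rho[1]
          mu1 <- st$muR[1]
          s0 <- data$sigma_o_init
          have0 <- has0 && likelihood
          lpsi_n <- log(st$psi[psi_idx[n]])
          val_abs <- function(d) {
            if (n0 + d < lo || n0 + d > hi) return(-Inf)
            v <- -0.5 * ((r1 - d - mu1) / st$sigma_p_R)^2
            if (have0) {
              z <- (log(data$Y_init) -
                      (lpsi_n + n0 + d - s0^2 / 2)) / s0
              v <- v - 0.5 * w_lik * z^2
            }
            v
          }
          dlt <- slice_orbit(val_abs, w = 0.4)
          if (dlt != 0) {
            st$log_N_init <- n0 + dlt
            st$log_rho[1] <- r1 - dlt
            st$logN <- calc_logN()
            comp$rho <- lp_rho()
            comp$obs <- lp_obs()
            acc[b] <- acc[b] + 1L
          }
        } else {
          or <- orbits[[k]]
          phis <- lapply(or$js, function(j)
            1 / (1 + exp(-st$logit_phi[j, ])))
          psi_s <- unname(st$psi[s])
          rho_aff <- or$drho1 != 0 || or$drho2 != 0
          have0 <- or$n_in_I && has0 && likelihood
          eval_orbit <- function(d) {
            # returns either -Inf (off support) or the pushforward value
            # plus the proposed state pieces
            psi_new <- psi_s * exp(d)
            v <- d + prior_logpdf_1(or$psi_prior, psi_new)
            if (!is.finite(v)) return(list(v = -Inf))
            lg <- list()
            bsh <- list()
            for (idx in seq_along(or$js)) {
              j <- or$js[idx]
              dp <- or$dphi[j] * d
              phin <- phis[[idx]] * exp(dp)
              if (any(phin >= 1 - 1e-12)) return(list(v = -Inf))
              lgn <- log(phin) - log1p(-phin)
              lg[[idx]] <- lgn
              v <- v + sum(log1p(-phis[[idx]]) - log1p(-phin))
              mu_j <- st$muS[j, ]
              cmp <- or$comp[[idx]]
              if (length(cmp$Jb)) {
                bs <- drop(cmp$proj %*% (lgn - st$logit_phi[j, ]))
                bsh[[idx]] <- bs
                mu_j <- mu_j + drop(cmp$W %*% bs)
                for (q in seq_along(cmp$Jb))
                  v <- v + prior_logpdf_1(cmp$priors[[q]],
                                          st$beta_S[[j]][cmp$Jb[q]] + bs[q])
              } else bsh[idx] <- list(NULL)
              v <- v - 0.5 * sum(((lgn - mu_j) / st$sigma_p_S[j])^2)
            }
            bshR <- NULL
            if (rho_aff) {
              drho <- c(or$drho1 * d, rep(or$drho2 * d, T - 1L))
              muR_new <- st$muR
              if (length(or$compR$Jb)) {
                bshR <- drop(or$compR$proj %*% drho)
                muR_new <- muR_new + drop(or$compR$W %*% bshR)
                for (q in seq_along(or$compR$Jb))
                  v <- v + prior_logpdf_1(or$compR$priors[[q]],
                                          st$beta_R[or$compR$Jb[q]] + bshR[q])
              }
              v <- v - 0.5 * sum(((st$log_rho + drho - muR_new) /
                                    st$sigma_p_R)^2)
              if (have0) {
                s0 <- data$sigma_o_init
                z <- (log(data$Y_init) -
                        (log(psi_new) + st$log_N_init - s0^2 / 2)) / s0
                v <- v - 0.5 * w_lik * z^2
              }
            }
            list(v = v, psi_new = psi_new, lg = lg, bsh = bsh, bshR = bshR)
          }
          val_abs <- function(d) eval_orbit(d)$v
          dlt <- slice_orbit(val_abs, w = 0.4)
          prop_state <- if (dlt != 0) eval_orbit(dlt) else list(v = -Inf)
          if (is.finite(prop_state$v)) {
            st$psi[s] <- prop_state$psi_new
            for (idx in seq_along(or$js)) {
              j <- or$js[idx]
              st$logit_phi[j, ] <- prop_state$lg[[idx]]
              cmp <- or$comp[[idx]]
              if (length(cmp$Jb)) {
                bs <- prop_state$bsh[[idx]]
                st$beta_S[[j]][cmp$Jb] <- st$beta_S[[j]][cmp$Jb] + bs
                st$muS[j, ] <- st$muS[j, ] + drop(cmp$W %*% bs)
              }
            }
            if (rho_aff) {
              st$log_rho <- st$log_rho +
                c(or$drho1 * dlt, rep(or$drho2 * dlt, T - 1L))
              if (length(or$compR$Jb)) {
                bsR <- prop_state$bshR
                st$beta_R[or$compR$Jb] <- st$beta_R[or$compR$Jb] + bsR
                st$muR <- st$muR + drop(or$compR$W %*% bsR)
              }
            }
            st$logN <- calc_logN()
            comp$rho <- lp_rho()
            comp$phi <- vapply(seq_len(n - 1L), lp_phi, 0)
            comp$obs <- lp_obs()
            acc[b] <- acc[b] + 1L
          }
        }
      } else if (types[b] == "sweep") { # sweep move
        mv <- sweep_moves[[blocks[b]]]
        a <- acc_list[[mv$nm]]
        old <- a$get()
        delta <- scales[b] * stats::rnorm(1)
        lp_old <- prior_logpdf_1(a$prior, old)
        old_logN <- st$logN
        if (!is.null(mv$x)) {
          # coefficient translation: latent row moves with the regression
          # mean, process residuals unchanged, Jacobian 1
          prop <- old + delta
          lp_new <- prior_logpdf_1(a$prior, prop)
          if (!is.finite(lp_new)) next
          a$set(prop)
          if (mv$rate == 0L) st$log_rho <- st$log_rho + delta * mv$x
          else st$logit_phi[mv$rate, ] <- st$logit_phi[mv$rate, ] +
              delta * mv$x
          st$logN <- calc_logN()
          new_obs <- lp_obs()
          if (log_accept(lp_new + new_obs - lp_old - comp$obs)) {
            comp$obs <- new_obs
            # process terms are unchanged up to rounding; refresh the cache
            comp$rho <- lp_rho()
            comp$phi <- vapply(seq_len(n - 1L), lp_phi, 0)
            acc[b] <- acc[b] + 1L
          } else {
            a$set(old)
            if (mv$rate == 0L) st$log_rho <- st$log_rho - delta * mv$x
            else st$logit_phi[mv$rate, ] <- st$logit_phi[mv$rate, ] -
                delta * mv$x
            st$logN <- old_logN
          }
        } else {
          # process-SD rescale: residuals scale with the SD; the latent
          # Jacobian T*delta cancels the process-density change, leaving
          # prior, observation and the SD's own Jacobian term
          prop <- old * exp(delta)
          lp_new <- prior_logpdf_1(a$prior, prop)
          if (!is.finite(lp_new)) next
          old_lat <- if (mv$rate == 0L) st$log_rho else st$logit_phi[mv$rate, ]
          mu <- if (mv$rate == 0L) st$muR else st$muS[mv$rate, ]
          a$set(prop)
          new_lat <- mu + exp(delta) * (old_lat - mu)
          if (mv$rate == 0L) st$log_rho <- new_lat
          else st$logit_phi[mv$rate, ] <- new_lat
          st$logN <- calc_logN()
          new_obs <- lp_obs()
          if (log_accept(lp_new + new_obs + delta - lp_old - comp$obs)) {
            comp$obs <- new_obs
            comp$rho <- lp_rho()
            comp$phi <- vapply(seq_len(n - 1L), lp_phi, 0)
            acc[b] <- acc[b] + 1L
          } else {
            a$set(old)
            if (mv$rate == 0L) st$log_rho <- old_lat
            else st$logit_phi[mv$rate, ] <- old_lat
            st$logN <- old_logN
          }
        }
      } else if (types[b] == "grand") {
        # grand move: correlated jump of the whole parameter block with the
        # latent states carried along in non-centered form (standardized
        # process residuals held fixed); the latent Jacobian cancels the
        # process-density change, leaving prior, observation and the
        # scalar link Jacobians
        logq_corr <- 0
        mix <- c(0.33, 1, 3)[sample.int(3L, 1L, prob = c(0.25, 0.5, 0.25))]
        delta <- mix * scales[b] * drop(stats::rnorm(n_free) %*% prop_L)
        keep <- list(log_N_init = st$log_N_init, beta_R = st$beta_R,
                     beta_S = st$beta_S, sigma_p_R = st$sigma_p_R,
                     sigma_p_S = st$sigma_p_S, psi = st$psi,
                     log_rho = st$log_rho, logit_phi = st$logit_phi,
                     muR = st$muR, muS = st$muS, logN = st$logN)
        lp_old_prior <- 0
        lp_new_prior <- 0
        bad <- FALSE
        for (j in seq_len(n_free)) {
          a <- acc_list[[j]]
          old_v <- a$get()
          new_v <- if (grand_sigma[j] || grand_psi[j]) old_v * exp(delta[j])
                   else old_v + delta[j]
          lp_old_prior <- lp_old_prior + prior_logpdf_1(a$prior, old_v)
          pnew <- prior_logpdf_1(a$prior, new_v)
          if (!is.finite(pnew)) { bad <- TRUE; break }
          lp_new_prior <- lp_new_prior + pnew
          a$set(new_v)
        }
        if (bad) {
          st$log_N_init <- keep$log_N_init; st$beta_R <- keep$beta_R
          st$beta_S <- keep$beta_S; st$sigma_p_R <- keep$sigma_p_R
          st$sigma_p_S <- keep$sigma_p_S; st$psi <- keep$psi
          st$muR <- keep$muR; st$muS <- keep$muS
          next
        }
        # reconstruct latent rows from the preserved standardized residuals
        st$log_rho <- st$muR + (st$sigma_p_R / keep$sigma_p_R) *
          (keep$log_rho - keep$muR)
        for (i in seq_len(n - 1L))
          st$logit_phi[i, ] <- st$muS[i, ] +
            (st$sigma_p_S[i] / keep$sigma_p_S[i]) *
            (keep$logit_phi[i, ] - keep$muS[i, ])
        st$logN <- calc_logN()
        new_obs <- lp_obs()
        log_jac <- sum(delta[grand_sigma | grand_psi])
        if (log_accept(lp_new_prior + new_obs + log_jac + logq_corr -
                         lp_old_prior - comp$obs)) {
          comp$obs <- new_obs
          comp$rho <- lp_rho()
          comp$phi <- vapply(seq_len(n - 1L), lp_phi, 0)
          acc[b] <- acc[b] + 1L
        } else {
          st$log_N_init <- keep$log_N_init; st$beta_R <- keep$beta_R
          st$beta_S <- keep$beta_S; st$sigma_p_R <- keep$sigma_p_R
          st$sigma_p_S <- keep$sigma_p_S; st$psi <- keep$psi
          st$log_rho <- keep$log_rho; st$logit_phi <- keep$logit_phi
          st$muR <- keep$muR; st$muS <- keep$muS; st$logN <- keep$logN
        }
      } else if (types[b] == "indep") { # independence move: parameters proposed from the frozen
        # pilot-based multivariate t, latent states from the Laplace
        # conditional Gaussian at the proposed parameters. An accepted move
        # regenerates the whole state, resetting autocorrelation along the
        # posterior's confounding ridges. Attempted every fourth iteration
        # (it is the costliest move) and only at full likelihood weight so
        # the cached annealed target stays consistent.
        if (w_lik < 1 || iter %% 4L != 0L) next
        xi_old <- link_xi()
        w <- stats::rchisq(1, indep$df)
        xi_new <- indep$m +
          drop(stats::rnorm(n_free) %*% indep$L) / sqrt(w / indep$df)
        delta <- xi_new - xi_old
        # evaluate prior at the proposed parameters
        lp_old_prior <- 0
        lp_new_prior <- 0
        bad <- FALSE
        prop_vals <- numeric(n_free)
        for (j in seq_len(n_free)) {
          a <- acc_list[[j]]
          old_v <- a$get()
          new_v <- if (grand_sigma[j] || grand_psi[j]) exp(xi_new[j])
                   else xi_new[j]
          prop_vals[j] <- new_v
          lp_old_prior <- lp_old_prior + prior_logpdf_1(a$prior, old_v)
          pnew <- prior_logpdf_1(a$prior, new_v)
          if (!is.finite(pnew)) { bad <- TRUE; break }
          lp_new_prior <- lp_new_prior + pnew
        }
        if (bad) next
        u_cur <- c(st$log_rho, as.vector(st$logit_phi))
        par_cur <- st_params()
        lap_cur <- laplace_u(par_cur, u_cur)
        if (is.null(lap_cur)) next
        keep <- list(log_N_init = st$log_N_init, beta_R = st$beta_R,
                     beta_S = st$beta_S, sigma_p_R = st$sigma_p_R,
                     sigma_p_S = st$sigma_p_S, psi = st$psi,
                     log_rho = st$log_rho, logit_phi = st$logit_phi,
                     muR = st$muR, muS = st$muS, logN = st$logN)
        for (j in seq_len(n_free)) acc_list[[j]]$set(prop_vals[j])
        par_new <- st_params()
        lap_new <- laplace_u(par_new, lap_cur$u_hat)
        restore <- function() {
          st$log_N_init <- keep$log_N_init; st$beta_R <- keep$beta_R
          st$beta_S <- keep$beta_S; st$sigma_p_R <- keep$sigma_p_R
          st$sigma_p_S <- keep$sigma_p_S; st$psi <- keep$psi
          st$log_rho <- keep$log_rho; st$logit_phi <- keep$logit_phi
          st$muR <- keep$muR; st$muS <- keep$muS; st$logN <- keep$logN
        }
        if (is.null(lap_new)) { restore(); next }
        # carry the latent states by the shift of the conditional mode:
        # the residual u - u_hat(theta) is preserved, so the data-pinned
        # latent configuration survives the parameter jump (Jacobian 1)
        u_new <- u_cur + (lap_new$u_hat - lap_cur$u_hat)
        jn_new <- tryCatch(
          joint_nll_u_deriv(par_new, u_new, data, dep_cache = dep_D)$value,
          error = function(e) NA_real_)
        jn_cur <- joint_nll_u_deriv(par_cur, u_cur, data,
                                    dep_cache = dep_D)$value
        if (!is.finite(jn_new)) { restore(); next }
        # target in (link-parameter, latent) coordinates; t-proposal ratio
        log_ratio <- (-jn_new + lp_new_prior +
                        sum(xi_new[grand_sigma | grand_psi])) -
          (-jn_cur + lp_old_prior + sum(xi_old[grand_sigma | grand_psi])) +
          indep_logq(xi_old) - indep_logq(xi_new)
        if (isTRUE(getOption("stagebias.mcmc.debug")))
          cat(sprintf(
            "indep iter=%d jn_new=%.1f jn_cur=%.1f dprior=%.2f dq=%.1f lr=%.1f\n",
            iter, jn_new, jn_cur, lp_new_prior - lp_old_prior,
            indep_logq(xi_old) - indep_logq(xi_new), log_ratio))
        if (log_accept(log_ratio)) {
          st$log_rho <- u_new[seq_len(T)]
          st$logit_phi <- matrix(u_new[-seq_len(T)], n - 1L, T)
          st$logN <- calc_logN()
          comp$obs <- lp_obs()
          comp$rho <- lp_rho()
          comp$phi <- vapply(seq_len(n - 1L), lp_phi, 0)
          acc[b] <- acc[b] + 1L
        } else restore()
      } else if (types[b] == "gbeta") {
        # exact Gibbs draw of a vital rate's free coefficients given its
        # latent row (conjugate Gaussian; the observation model does not
        # involve the coefficients)
        g <- gibbs_beta[[blocks[b]]]
        y <- if (g$rate == 0L) st$log_rho else st$logit_phi[g$rate, ]
        sig <- if (g$rate == 0L) st$sigma_p_R else st$sigma_p_S[g$rate]
        beta_full <- if (g$rate == 0L) st$beta_R else st$beta_S[[g$rate]]
        if (length(g$J) < length(beta_full))
          y <- y - drop(g$W[, -g$J, drop = FALSE] %*% beta_full[-g$J])
        Wj <- g$W[, g$J, drop = FALSE]
        Q <- crossprod(Wj) / sig^2
        diag(Q) <- diag(Q) + g$tau
        bvec <- drop(crossprod(Wj, y)) / sig^2 + g$tau * g$mu0
        Rq <- chol(Q)
        mn <- backsolve(Rq, forwardsolve(t(Rq), bvec))
        beta_full[g$J] <- mn + backsolve(Rq, stats::rnorm(length(g$J)))
        if (g$rate == 0L) {
          st$beta_R <- beta_full
          st$muR <- drop(g$W %*% beta_full)
          comp$rho <- lp_rho()
        } else {
          st$beta_S[[g$rate]] <- beta_full
          st$muS[g$rate, ] <- drop(g$W %*% beta_full)
          comp$phi[g$rate] <- lp_phi(g$rate)
        }
        acc[b] <- acc[b] + 1L
      } else { # gn0: Gibbs draw of the initial log-abundance
        # every observation mean is linear in log N[n,0] with coefficient
        # one; the conditional is Gaussian truncated to the uniform prior
        w_eff <- if (likelihood) w_lik else 0
        lpsi <- log(st$psi)
        path <- st$logN - st$log_N_init
        r_obs <- o_logy - (lpsi[o_psi] + path[o_lin] - o_half)
        P <- w_eff * sum(1 / o_s^2)
        mn <- w_eff * sum(r_obs / o_s^2)
        if (has0) {
          s0 <- data$sigma_o_init
          r0 <- log(data$Y_init) - (lpsi[psi_idx[n]] - s0^2 / 2)
          P <- P + w_eff / s0^2
          mn <- mn + w_eff * r0 / s0^2
        }
        lo <- priors$log_N_init$lower
        hi <- priors$log_N_init$upper
        draw <- if (P < 1e-12) stats::runif(1, lo, hi) else {
          mu <- mn / P
          sd <- 1 / sqrt(P)
          plo <- stats::pnorm(lo, mu, sd)
          phi_hi <- stats::pnorm(hi, mu, sd)
          if (phi_hi - plo < 1e-14) min(max(mu, lo), hi)
          else stats::qnorm(stats::runif(1, plo, phi_hi), mu, sd)
        }
        dlt <- draw - st$log_N_init
        st$log_N_init <- draw
        st$logN <- st$logN + dlt
        comp$obs <- lp_obs()
        acc[b] <- acc[b] + 1L
      }
    }
    if (iter <= burn_in) {
      hist_xi[iter, ] <- link_xi()
      if (iter %% 500L == 0L && iter >= anneal_len + 1000L) {
        h <- hist_xi[(anneal_len + 1L):iter, , drop = FALSE]
        S <- stats::cov(h) + diag(1e-10, n_free)
        ch_try <- tryCatch(chol(S), error = function(e) NULL)
        if (!is.null(ch_try)) prop_L <- ch_try
      }
    }
    # adapt proposal scales in batches of 50, burn-in only
    if (iter <= burn_in && iter %% 50L == 0L) {
      batch <- batch + 1L
      rate <- acc / pmax(tries, 1L)
      delta <- min(0.25, 1 / sqrt(batch))
      scales[adaptable] <- scales[adaptable] *
        exp(delta * (rate - target))[adaptable]
      acc[] <- 0L
      tries[] <- 0L
    }
    if (iter > burn_in)
      out[iter - burn_in, ] <- vapply(acc_list, function(a) a$get(), 0)
  }
  list(draws = out, accept = acc / pmax(tries, 1L))
}

log_accept <- function(log_ratio) {
  is.finite(log_ratio) && (log_ratio >= 0 || log(stats::runif(1)) < log_ratio)
}

# Univariate slice sampler (stepping out + shrinkage) for a log-density
# given relative to the current point (val_abs(0) is the current value).
slice_orbit <- function(val_abs, w = 0.4, max_step = 10L) {
  v0 <- val_abs(0)
  if (!is.finite(v0)) return(0)
  y <- v0 - stats::rexp(1)
  u0 <- stats::runif(1)
  L <- -w * u0
  R <- L + w
  for (k in seq_len(max_step)) {
    if (!is.finite(vl <- val_abs(L)) || vl <= y) break
    L <- L - w
  }
  for (k in seq_len(max_step)) {
    if (!is.finite(vr <- val_abs(R)) || vr <= y) break
    R <- R + w
  }
  for (k in seq_len(50L)) {
    d <- stats::runif(1, L, R)
    vd <- val_abs(d)
    if (is.finite(vd) && vd > y) return(d)
    if (d < 0) L <- d else R <- d
    if (R - L < 1e-12) break
  }
  0
}

# One resolved accessor record per free parameter: getter, setter (keeping
# cached process means in sync) and the cached likelihood component its
# updates touch. Indices and priors are resolved once, outside the hot loop.
make_accessors <- function(st, free, priors, cov) {
  build <- function(nm) {
    prior <- priors[[nm]]
    if (is.null(prior)) stop("no prior specified for ", nm)
    if (nm == "log_N_init")
      return(list(kind = "logN0", prior = prior,
                  get = function() st$log_N_init,
                  set = function(v) st$log_N_init <- v))
    if (nm == "sigma_p_R")
      return(list(kind = "rho", prior = prior,
                  get = function() st$sigma_p_R,
                  set = function(v) st$sigma_p_R <- v))
    m <- regmatches(nm, regexec("^sigma_p_S([0-9]+)$", nm))[[1]]
    if (length(m)) {
      i <- as.integer(m[2])
      return(list(kind = "phi", i = i, prior = prior,
                  get = function() st$sigma_p_S[i],
                  set = function(v) st$sigma_p_S[i] <- v))
    }
    m <- regmatches(nm, regexec("^beta_R_([0-9]+)$", nm))[[1]]
    if (length(m)) {
      j <- as.integer(m[2]) + 1L
      return(list(kind = "rho", prior = prior,
                  get = function() st$beta_R[j],
                  set = function(v) {
                    st$beta_R[j] <- v
                    st$muR <- drop(cov$w_R %*% st$beta_R)
                  }))
    }
    m <- regmatches(nm, regexec("^beta_S([0-9]+)_([0-9]+)$", nm))[[1]]
    if (length(m)) {
      i <- as.integer(m[2])
      j <- as.integer(m[3]) + 1L
      return(list(kind = "phi", i = i, prior = prior,
                  get = function() st$beta_S[[i]][j],
                  set = function(v) {
                    st$beta_S[[i]][j] <- v
                    st$muS[i, ] <- drop(cov$w_S[[i]] %*% st$beta_S[[i]])
                  }))
    }
    m <- regmatches(nm, regexec("^psi_(.+)$", nm))[[1]]
    if (length(m)) {
      s <- m[2]
      return(list(kind = "psi", prior = prior,
                  get = function() unname(st$psi[s]),
                  set = function(v) st$psi[s] <- v))
    }
    stop("unknown parameter: ", nm)
  }
  lapply(stats::setNames(free, free), build)
}
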