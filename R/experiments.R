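# Simulation experiments: consequences of ignoring or misspecifying
# observation bias, vital-rate prediction curves, and the profile-likelihood
# grid scan over confounded intercept parameters.

#' Adjusted true values under a (possibly wrong) reference bias
#'
#' When the reference survey `j`'s bias is fixed at `psi_ref` rather than its
#' true value, the likelihood is maximized near a rescaled truth: the
#' initial abundance converges to `N[n,0] * psi_j / psi_ref` and each free
#' bias to `psi_i * psi_ref / psi_j`. These rescaled values are the correct
#' targets when scoring estimates, and ratios of free biases are unaffected.
#'
#' @param true_params The generating [lifecycle_params()].
#' @param ref_survey Survey label of the fixed (reference) bias parameter.
#' @param psi_ref The value it was fixed at.
#' @return A list with `log_N_init`, `N_init` and `psi` (free surveys only),
#'   all on the adjusted scale.
#' @export
adjusted_true_values <- function(true_params, ref_survey, psi_ref = 1) {
  if (!ref_survey %in% names(true_params$psi))
    stop("unknown reference survey: ", ref_survey)
  if (psi_ref <= 0) stop("psi_ref must be positive")
  psi_j <- unname(true_params$psi[ref_survey])
  free <- setdiff(names(true_params$psi), ref_survey)
  list(log_N_init = true_params$log_N_init + log(psi_j / psi_ref),
       N_init = exp(true_params$log_N_init) * psi_j / psi_ref,
       psi = true_params$psi[free] * psi_ref / psi_j)
}

# Natural-scale truth vector for scoring a fit of the given model spec.
scoring_truth <- function(true_params, fix_psi) {
  free_psi <- setdiff(names(true_params$psi), names(fix_psi))
  truth <- c(N_init = exp(true_params$log_N_init),
             stats::setNames(true_params$beta_R,
                             paste0("beta_R_", seq_along(true_params$beta_R) - 1L)),
             unlist(lapply(seq_along(true_params$beta_S), function(i)
               stats::setNames(true_params$beta_S[[i]],
                               paste0("beta_S", i, "_",
                                      seq_along(true_params$beta_S[[i]]) - 1L)))),
             sigma_p_R = true_params$sigma_p_R,
             stats::setNames(true_params$sigma_p_S,
                             paste0("sigma_p_S",
                                    seq_along(true_params$sigma_p_S))),
             if (length(free_psi))
               stats::setNames(unname(true_params$psi[free_psi]),
                               paste0("psi_", free_psi)))
  if (length(free_psi) && length(fix_psi)) {
    # single reference survey: score against the rescaled truth
    adj <- adjusted_true_values(true_params, names(fix_psi)[1],
                                unname(fix_psi[1]))
    truth["N_init"] <- adj$N_init
    truth[paste0("psi_", free_psi)] <- adj$psi[free_psi]
  }
  truth
}

fit_estimates <- function(fit) {
  th <- fit$theta_hat
  free_psi <- setdiff(names(th$psi), names(fit$fix_psi))
  c(N_init = exp(th$log_N_init),
    stats::setNames(th$beta_R, paste0("beta_R_", seq_along(th$beta_R) - 1L)),
    unlist(lapply(seq_along(th$beta_S), function(i)
      stats::setNames(th$beta_S[[i]],
                      paste0("beta_S", i, "_",
                             seq_along(th$beta_S[[i]]) - 1L)))),
    sigma_p_R = th$sigma_p_R,
    stats::setNames(th$sigma_p_S,
                    paste0("sigma_p_S", seq_along(th$sigma_p_S))),
    if (length(free_psi))
      stats::setNames(unname(th$psi[free_psi]), paste0("psi_", free_psi)))
}

#' Simulate-and-refit study of bias misspecification
#'
#' Repeatedly simulates datasets under a scenario and fits one of the two
#' model types: all bias parameters fixed at 1 (`"fix_all"`), or the
#' stage-4 survey's bias fixed at 1 with the rest estimated (`"fix_ref"`).
#' Replicates whose fit converges with a non-positive-definite Hessian are
#' replaced by a freshly simulated dataset, up to `retry_cap` attempts per
#' slot. Estimates are scored against the adjusted true values of
#' [adjusted_true_values()] (relevant when the reference bias is fixed at a
#' wrong value), using relative error `(est - true) / |true|`.
#'
#' @param n_reps Number of scored replicates.
#' @param spec A [scenario_spec()] defining the generating parameters.
#' @param model `"fix_all"`, `"fix_ref"`, or a named numeric vector passed
#'   as `fix_psi` to [fit_mle()].
#' @param seed Integer master seed.
#' @param retry_cap Maximum simulation attempts per replicate slot.
#' @return An object of class `"sim_study"`: per-parameter summary
#'   (`summary`: mean estimate, relative bias, MSE, sampling SD), the raw
#'   estimate matrix, and retry/failure counts.
#' @export
run_bias_study <- function(n_reps, spec, model = c("fix_all", "fix_ref"),
                           seed = 1L, retry_cap = 10L) {
  stopifnot(inherits(spec, "scenario_spec"))
  true_params <- preset_params(spec)
  sigma_o <- attr(true_params, "sigma_o")
  sv <- names(true_params$psi)
  if (is.character(model)) {
    model <- match.arg(model)
    fix_psi <- if (model == "fix_all")
      stats::setNames(rep(1, length(sv)), sv)
    else stats::setNames(1, sv[spec$n_stages])
  } else fix_psi <- model
  truth <- scoring_truth(true_params, fix_psi)
  seeds <- child_seeds(seed, n_reps * (retry_cap + 1L))
  est <- matrix(NA_real_, n_reps, length(truth),
                dimnames = list(NULL, names(truth)))
  n_retries <- 0L
  n_failed <- 0L
  for (r in seq_len(n_reps)) {
    ok <- FALSE
    for (a in seq_len(retry_cap + 1L)) {
      s <- child_seeds(seeds[(r - 1L) * (retry_cap + 1L) + a], 2L)
      cov <- simulate_covariates(spec$T, spec$n_stages, 1L, seed = s[1])
      sim <- simulate_dataset(true_params, cov, sigma_o, seed = s[2])
      fit <- tryCatch(
        fit_mle(sim$data, fix_psi = fix_psi, light = TRUE),
        error = function(e) NULL)
      if (!is.null(fit) && fit$converged && fit$hessian_pd) {
        est[r, ] <- fit_estimates(fit)[names(truth)]
        ok <- TRUE
        break
      }
      n_retries <- n_retries + 1L
    }
    if (!ok) n_failed <- n_failed + 1L
  }
  scored <- est[stats::complete.cases(est), , drop = FALSE]
  rel <- sweep(sweep(scored, 2, truth), 2, abs(truth), "/")
  err <- sweep(scored, 2, truth)
  summary <- data.frame(
    parameter = names(truth),
    true = unname(truth),
    mean_est = colMeans(scored),
    rel_bias = colMeans(rel),
    mse = colMeans(err^2),
    sd = apply(scored, 2, stats::sd),
    row.names = NULL)
  structure(list(summary = summary, estimates = est,
                 pairing = list(biased = spec$biased,
                                info_level = spec$info_level,
                                fix_psi = fix_psi),
                 truth = truth, n_reps = n_reps, n_retries = n_retries,
                 n_failed = n_failed),
            class = "sim_study")
}

#' @export
print.sim_study <- function(x, ...) {
  cat(sprintf(
    "Bias simulation study: %d replicates (%d retries, %d failed slots)\n",
    x$n_reps, x$n_retries, x$n_failed))
  cat(sprintf("  data %s, model fixes psi: %s\n",
              if (x$pairing$biased) "biased" else "unbiased",
              paste(names(x$pairing$fix_psi), collapse = ", ")))
  print(x$summary, digits = 3)
  invisible(x)
}

#' Vital-rate prediction curves with process-stochasticity bands
#'
#' For each vital rate and each of its covariates, simulates realizations of
#' the rate at the fitted parameters over a grid of covariate values (the
#' other covariates held at their means) and summarizes the mean and the
#' 2.5/97.5 percentiles. The bands describe process stochasticity only.
#'
#' @param fit An [fit_mle()] result.
#' @param grids Optional named list (`"R"`, `"S1"`, ...) of covariate grids;
#'   defaults to 21 points spanning the observed covariate range.
#' @param n_draws Simulated realizations per grid point.
#' @param seed Optional integer seed.
#' @return A data.frame of class `"vital_rate_curves"` with columns
#'   `vital_rate`, `covariate`, `x`, `mean`, `lo`, `hi`.
#' @export
vital_rate_curves <- function(fit, grids = NULL, n_draws = 10000L,
                              seed = NULL) {
  th <- fit$theta_hat
  cov <- fit$data$covariates
  rates <- c(list(R = list(w = cov$w_R, beta = th$beta_R,
                           sigma = th$sigma_p_R, link = exp)),
             stats::setNames(lapply(seq_len(th$n_stages - 1L), function(i)
               list(w = cov$w_S[[i]], beta = th$beta_S[[i]],
                    sigma = th$sigma_p_S[i], link = invlogit)),
               paste0("S", seq_len(th$n_stages - 1L))))
  with_seed(seed, {
    out <- list()
    for (nm in names(rates)) {
      r <- rates[[nm]]
      n_cov <- ncol(r$w) - 1L
      for (j in seq_len(n_cov)) {
        xg <- if (!is.null(grids[[nm]])) grids[[nm]]
              else seq(min(r$w[, j + 1L]), max(r$w[, j + 1L]),
                       length.out = 21L)
        base <- c(1, colMeans(r$w[, -1L, drop = FALSE]))
        for (x in xg) {
          w <- base
          w[j + 1L] <- x
          eta <- sum(w * r$beta)
          draws <- r$link(stats::rnorm(n_draws, eta, r$sigma))
          qs <- stats::quantile(draws, c(0.025, 0.975))
          out[[length(out) + 1L]] <- data.frame(
            vital_rate = nm, covariate = j, x = x,
            mean = mean(draws), lo = qs[1], hi = qs[2])
        }
      }
    }
    structure(do.call(rbind, c(out, make.row.names = FALSE)),
              n_draws = n_draws,
              class = c("vital_rate_curves", "data.frame"))
  })
}

#' Profile-likelihood grid scan over confounded intercepts
#'
#' Fixes a triplet (in general, a tuple) of intercept parameters at each
#' point of a rectangular grid, re-optimizes all remaining free parameters,
#' and retains the grid points whose profile likelihood is not rejected by a
#' likelihood-ratio test against the unconstrained fit. The retained cloud
#' maps out the likelihood ridge that the local covariance matrix
#' understates when parameters are practically confounded.
#'
#' @param fit An [fit_mle()] result.
#' @param params Free-parameter coordinate names to scan (default the
#'   recruitment and first two survival intercepts).
#' @param bounds List (or 2-row matrix) of finite `c(lower, upper)` bounds
#'   per scanned parameter. Bounds are configuration inputs (e.g. a
#'   fecundity cap, a survival floor), not computed here.
#' @param grid_n Points per dimension, endpoints included.
#' @param alpha LRT rejection level; degrees of freedom equal the number of
#'   scanned parameters.
#' @param curves If `TRUE`, also compute [vital_rate_curves()] at each
#'   retained grid point.
#' @param n_draws Draws per curve when `curves = TRUE`.
#' @return An object of class `"grid_scan"`: the grid with `loglik`,
#'   `converged` and `retained` columns, the LRT threshold used, the count
#'   of failed points, constrained parameter sets for retained points, and
#'   optionally their curves.
#' @export
intercept_grid_scan <- function(fit, params = c("beta_R_0", "beta_S1_0",
                                                "beta_S2_0"),
                                bounds, grid_n = 10L, alpha = 0.05,
                                curves = FALSE, n_draws = 1000L) {
  if (!all(params %in% fit$free_names))
    stop("scanned parameters must be free in the fit")
  if (is.matrix(bounds))
    bounds <- lapply(seq_len(ncol(bounds)), function(j) bounds[, j])
  stopifnot(length(bounds) == length(params),
            all(vapply(bounds, function(b) all(is.finite(b)), TRUE)))
  axes <- lapply(bounds, function(b) seq(b[1], b[2], length.out = grid_n))
  grid <- do.call(expand.grid, stats::setNames(axes, params))
  # visit outward from the MLE, warm-starting from the nearest solved point
  span <- vapply(bounds, function(b) max(b[2] - b[1], 1e-12), 0)
  sc <- function(g) sweep(as.matrix(g), 2, span, "/")
  mle_pt <- sweep(matrix(fit$par[params], 1), 2, span, "/")
  ord <- order(sqrt(rowSums(sweep(sc(grid), 2, drop(mle_pt))^2)))
  loglik <- rep(NA_real_, nrow(grid))
  conv <- rep(FALSE, nrow(grid))
  thetas <- vector("list", nrow(grid))
  done <- integer(0)
  for (r in ord) {
    start <- fit$theta_hat
    if (length(done)) {
      d2 <- rowSums(sweep(sc(grid[done, , drop = FALSE]), 2,
                          drop(sc(grid[r, , drop = FALSE])))^2)
      nearest <- done[which.min(d2)]
      if (!is.null(thetas[[nearest]])) start <- thetas[[nearest]]
    }
    f <- tryCatch(
      fit_mle(fit$data, fix_psi = fit$fix_psi,
              fix_log_N_init = fit$fix_log_N_init, start = start,
              fix_coords = c(fit$fix_coords,
                             stats::setNames(as.numeric(grid[r, ]), params)),
              surv_lognormal = fit$surv_lognormal),
      error = function(e) NULL)
    if (!is.null(f)) {
      loglik[r] <- f$loglik
      conv[r] <- f$converged
      thetas[[r]] <- f$theta_hat
    }
    done <- c(done, r)
  }
  df <- length(params)
  threshold <- stats::qchisq(1 - alpha, df)
  dev <- 2 * (fit$loglik - loglik)
  retained <- conv & !is.na(dev) & dev <= threshold
  out <- cbind(grid, loglik = loglik, deviance = dev, converged = conv,
               retained = retained)
  curve_list <- NULL
  if (curves) {
    curve_list <- lapply(which(retained), function(r) {
      f <- fit
      f$theta_hat <- thetas[[r]]
      vital_rate_curves(f, n_draws = n_draws, seed = r)
    })
    names(curve_list) <- which(retained)
  }
  structure(list(points = out, params = params, threshold = threshold,
                 df = df, alpha = alpha, mle_loglik = fit$loglik,
                 n_failed = sum(!conv), thetas = thetas[retained],
                 curves = curve_list),
            class = "grid_scan")
}

#' @export
print.grid_scan <- function(x, ...) {
  cat(sprintf(
    "Intercept grid scan over (%s): %d points, %d retained (LRT df=%d, chi2 cutoff %.2f), %d failed\n",
    paste(x$params, collapse = ", "), nrow(x$points),
    sum(x$points$retained), x$df, x$threshold, x$n_failed))
  invisible(x)
}
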