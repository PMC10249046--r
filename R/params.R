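#' Life-cycle model parameter set
#'
#' Bundles the full parameter vector of the sequential life-stage state-space
#' model: the initial log-abundance of reproducing adults, the recruitment and
#' survival regression coefficients, the process standard deviations on the
#' log (recruitment) and logit (survival) scales, and one multiplicative
#' observation-bias parameter per survey.
#'
#' @param n_stages Number of life stages `n` (>= 2). Stage `n` reproduces and
#'   dies; stages `1..n-1` survive to the next stage with cohort-specific
#'   probabilities.
#' @param log_N_init Log of the initial adult abundance `N[n,0]`.
#' @param beta_R Numeric vector of recruitment coefficients (intercept first).
#' @param beta_S List of `n_stages - 1` numeric vectors of survival
#'   coefficients (intercept first).
#' @param sigma_p_R Recruitment process SD on the log scale (> 0).
#' @param sigma_p_S Numeric vector of `n_stages - 1` survival process SDs on
#'   the logit scale (> 0).
#' @param psi Named positive vector of observation-bias parameters, one per
#'   survey. `psi` relates the true latent abundance to the expected value of
#'   its index: `E[Y] = psi * N`. Unnamed vectors are labelled
#'   `"S1".."Sn"`, one survey per stage.
#' @param psi_fixed Logical vector (same length/names as `psi`): `TRUE`
#'   entries are held fixed at their `psi` value during fitting. At least one
#'   bias parameter (or the initial abundance) must be fixed for the model to
#'   be identifiable.
#'
#' @return An object of class `"lifecycle_params"`.
#' @export
lifecycle_params <- function(n_stages, log_N_init, beta_R, beta_S,
                             sigma_p_R, sigma_p_S, psi,
                             psi_fixed = rep(FALSE, length(psi))) {
  n_stages <- as.integer(n_stages)
  if (n_stages < 2L) stop("n_stages must be >= 2")
  if (!is.list(beta_S) || length(beta_S) != n_stages - 1L)
    stop("beta_S must be a list of length n_stages - 1")
  if (length(sigma_p_S) != n_stages - 1L)
    stop("sigma_p_S must have length n_stages - 1")
  if (sigma_p_R <= 0 || any(sigma_p_S <= 0))
    stop("process SDs must be strictly positive")
  if (any(psi <= 0)) stop("bias parameters psi must be strictly positive")
  if (is.null(names(psi))) names(psi) <- paste0("S", seq_along(psi))
  if (length(psi_fixed) != length(psi))
    stop("psi_fixed must match psi in length")
  names(psi_fixed) <- names(psi)
  structure(list(
    n_stages = n_stages,
    log_N_init = as.numeric(log_N_init),
    beta_R = as.numeric(beta_R),
    beta_S = lapply(beta_S, as.numeric),
    sigma_p_R = as.numeric(sigma_p_R),
    sigma_p_S = as.numeric(sigma_p_S),
    psi = psi,
    psi_fixed = psi_fixed
  ), class = "lifecycle_params")
}

#' @export
print.lifecycle_params <- function(x, ...) {
  cat("Life-cycle SSM parameters:", x$n_stages, "stages\n")
  cat("  log N[n,0]:", format(x$log_N_init), "\n")
  cat("  beta_R:    ", paste(format(x$beta_R), collapse = " "), "\n")
  for (i in seq_along(x$beta_S))
    cat(sprintf("  beta_S%d:    %s\n", i,
                paste(format(x$beta_S[[i]]), collapse = " ")))
  cat("  sigma_p:   ", paste(format(c(x$sigma_p_R, x$sigma_p_S)),
                             collapse = " "), "\n")
  cat("  psi:       ", paste(sprintf("%s=%s%s", names(x$psi), format(x$psi),
                                     ifelse(x$psi_fixed, "*", "")),
                             collapse = " "),
      " (* = fixed)\n")
  invisible(x)
}

#' Covariate design matrices for the vital rates
#'
#' One design matrix per vital rate: recruitment and each of the `n - 1`
#' survival transitions. Each matrix has one row per cohort and an intercept
#' column of ones first.
#'
#' @param w_R Recruitment design matrix, `T x (m_R + 1)`.
#' @param w_S List of survival design matrices, each `T x (m_Si + 1)`.
#' @return An object of class `"covariate_set"`.
#' @export
covariate_set <- function(w_R, w_S) {
  w_R <- as.matrix(w_R)
  w_S <- lapply(w_S, as.matrix)
  T_n <- nrow(w_R)
  if (any(vapply(w_S, nrow, 1L) != T_n))
    stop("all design matrices must have the same number of rows (cohorts)")
  if (any(w_R[, 1] != 1) || any(vapply(w_S, function(w) any(w[, 1] != 1),
                                       TRUE)))
    stop("first column of every design matrix must be an intercept of ones")
  structure(list(w_R = w_R, w_S = w_S, T = T_n), class = "covariate_set")
}

#' Latent vital-rate states
#'
#' The latent states of the model on their transformed scales: log
#' recruitment rates `log(rho[t])` and logit survival probabilities
#' `logit(phi[i,t])`. Abundances are a deterministic function of these and
#' the initial abundance (see [build_abundances()]).
#'
#' @param log_rho Numeric vector of length `T`.
#' @param logit_phi Numeric matrix, `(n - 1) x T`.
#' @return An object of class `"latent_states"`.
#' @export
latent_states <- function(log_rho, logit_phi) {
  logit_phi <- as.matrix(logit_phi)
  if (ncol(logit_phi) != length(log_rho))
    stop("logit_phi must have one column per cohort (length of log_rho)")
  structure(list(log_rho = as.numeric(log_rho), logit_phi = logit_phi),
            class = "latent_states")
}

#' Observed abundance-index dataset
#'
#' Holds the index observations `Y[i,t]` (with missingness), their known
#' log-scale observation SDs, the stage-to-survey map that indexes the bias
#' parameters, and the covariates.
#'
#' @param Y `n x T` matrix of index values; `NA` marks a missing observation.
#' @param sigma_o `n x T` matrix of known log-scale observation SDs; must be
#'   finite and positive wherever `Y` is observed.
#' @param covariates A [covariate_set()].
#' @param survey_of_stage Character vector of length `n` mapping each stage to
#'   its survey label. Stages sharing a label share one bias parameter.
#' @param Y_init Optional observation of the initial adult abundance
#'   `N[n,0]`, taken with the stage-`n` survey.
#' @param sigma_o_init Log-scale observation SD for `Y_init`.
#' @return An object of class `"ssm_dataset"`.
#' @export
ssm_dataset <- function(Y, sigma_o, covariates,
                        survey_of_stage = paste0("S", seq_len(nrow(Y))),
                        Y_init = NA_real_, sigma_o_init = NA_real_) {
  Y <- as.matrix(Y)
  sigma_o <- as.matrix(sigma_o)
  n <- nrow(Y)
  if (!all(dim(Y) == dim(sigma_o)))
    stop("Y and sigma_o must have identical dimensions")
  if (!inherits(covariates, "covariate_set"))
    stop("covariates must be a covariate_set")
  if (ncol(Y) != covariates$T)
    stop("Y must have one column per cohort of the covariate set")
  if (length(survey_of_stage) != n)
    stop("survey_of_stage must have one entry per stage")
  obs <- !is.na(Y)
  if (any(Y[obs] <= 0))
    stop("observed index values must be strictly positive")
  if (any(!is.finite(sigma_o[obs]) | sigma_o[obs] <= 0))
    stop("sigma_o must be finite and positive wherever Y is observed")
  if (!is.na(Y_init)) {
    if (Y_init <= 0) stop("Y_init must be strictly positive")
    if (!is.finite(sigma_o_init) || sigma_o_init <= 0)
      stop("sigma_o_init must be finite and positive when Y_init is present")
  }
  structure(list(Y = Y, sigma_o = sigma_o, covariates = covariates,
                 survey_of_stage = as.character(survey_of_stage),
                 Y_init = Y_init, sigma_o_init = sigma_o_init,
                 n_stages = n, T = ncol(Y)),
            class = "ssm_dataset")
}

#' @export
print.ssm_dataset <- function(x, ...) {
  cat(sprintf("ssm_dataset: %d stages x %d cohorts, %d observations%s\n",
              x$n_stages, x$T, sum(!is.na(x$Y)),
              if (!is.na(x$Y_init)) " (+ initial adult index)" else ""))
  cat("  surveys:", paste(unique(x$survey_of_stage), collapse = ", "), "\n")
  invisible(x)
}

#' Number of non-missing observations in a dataset
#'
#' Counts index observations, including the initial adult index if present.
#' This is the effective sample size used by [aicc()].
#'
#' @param data An [ssm_dataset()].
#' @return Integer count.
#' @export
n_obs <- function(data) {
  sum(!is.na(data$Y)) + as.integer(!is.na(data$Y_init))
}

# Survey labels in stage order of first appearance; these index psi.
surveys_of <- function(data) unique(data$survey_of_stage)

# Check psi naming in params against the dataset's survey labels.
check_psi_surveys <- function(params, data) {
  sv <- surveys_of(data)
  if (!all(sv %in% names(params$psi)))
    stop("params$psi must be named with the dataset's survey labels: ",
         paste(setdiff(sv, names(params$psi)), collapse = ", "))
  invisible(TRUE)
}
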