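# Plain-text readers and writers. Observations travel as one CSV row per
# index value (cohort 0 = the initial adult index); covariates as a long
# table assembled into per-vital-rate design matrices.

#' Read abundance-index observations
#'
#' Expects a comma-separated file with header columns `cohort`, `stage`,
#' `survey`, `index`, `sd_log`; one row per observation. Cohorts absent for
#' a survey are treated as missing. A `cohort = 0` row for the last stage
#' carries the initial adult index. Cohorts need not be contiguous.
#'
#' @param path File path.
#' @param T Number of cohorts; defaults to the largest cohort seen.
#' @param n_stages Number of stages; defaults to the largest stage seen.
#' @return A list (a partial dataset) with `Y`, `sigma_o`,
#'   `survey_of_stage`, `Y_init`, `sigma_o_init`, `n_stages`, `T`; combine
#'   with covariates via [as_dataset()].
#' @export
read_observations <- function(path, T = NULL, n_stages = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cohort", "stage", "survey", "index", "sd_log")
  if (!all(need %in% names(df)))
    stop("observation file must have columns: ", paste(need, collapse = ", "))
  bad <- which(df$index <= 0 | df$sd_log <= 0 | !is.finite(df$index) |
                 !is.finite(df$sd_log))
  if (length(bad))
    stop("nonpositive index or sd_log at data line(s): ",
         paste(bad + 1L, collapse = ", "))
  n <- n_stages %||% max(df$stage)
  T <- T %||% max(df$cohort)
  Y <- matrix(NA_real_, n, T)
  sigma_o <- matrix(NA_real_, n, T)
  survey_of_stage <- rep(NA_character_, n)
  Y_init <- NA_real_
  sigma_o_init <- NA_real_
  for (r in seq_len(nrow(df))) {
    i <- df$stage[r]; t <- df$cohort[r]
    if (t == 0L) {
      if (i != n) stop("cohort 0 may only carry the initial stage-", n,
                       " index (line ", r + 1L, ")")
      Y_init <- df$index[r]
      sigma_o_init <- df$sd_log[r]
      next
    }
    if (i < 1 || i > n || t < 0 || t > T)
      stop("stage/cohort out of range at line ", r + 1L)
    if (!is.na(survey_of_stage[i]) && survey_of_stage[i] != df$survey[r])
      stop("stage ", i, " appears under two survey labels (line ", r + 1L,
           "); one survey per stage is supported")
    survey_of_stage[i] <- df$survey[r]
    Y[i, t] <- df$index[r]
    sigma_o[i, t] <- df$sd_log[r]
  }
  survey_of_stage[is.na(survey_of_stage)] <-
    paste0("S", which(is.na(survey_of_stage)))
  list(Y = Y, sigma_o = sigma_o, survey_of_stage = survey_of_stage,
       Y_init = Y_init, sigma_o_init = sigma_o_init, n_stages = n, T = T)
}

#' Write abundance-index observations
#'
#' Inverse of [read_observations()]; emits one row per non-missing
#' observation (and a `cohort = 0` row for the initial adult index).
#'
#' @param data An [ssm_dataset()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_observations <- function(data, path) {
  obs <- which(!is.na(data$Y), arr.ind = TRUE)
  df <- data.frame(cohort = obs[, 2], stage = obs[, 1],
                   survey = data$survey_of_stage[obs[, 1]],
                   index = data$Y[obs], sd_log = data$sigma_o[obs])
  if (!is.na(data$Y_init))
    df <- rbind(data.frame(cohort = 0L, stage = data$n_stages,
                           survey = data$survey_of_stage[data$n_stages],
                           index = data$Y_init,
                           sd_log = data$sigma_o_init), df)
  df <- df[order(df$cohort, df$stage), ]
  utils::write.csv(format(df, digits = 15, scientific = FALSE, trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read vital-rate covariates
#'
#' Long format with header `cohort`, `vital_rate`, `covariate`, `value`;
#' `vital_rate` is `"R"` for recruitment or `"S1".."S(n-1)"` for survival;
#' `covariate` numbers the covariates of that rate from 1. Rows may appear
#' in any order, but every cohort-by-covariate cell must be present (no
#' imputation is performed). Intercept columns are prepended.
#'
#' @param path File path.
#' @return A [covariate_set()].
#' @export
read_covariates <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cohort", "vital_rate", "covariate", "value")
  if (!all(need %in% names(df)))
    stop("covariate file must have columns: ", paste(need, collapse = ", "))
  T <- max(df$cohort)
  rates <- unique(df$vital_rate)
  s_rates <- sort(as.integer(sub("^S", "", rates[rates != "R"])))
  if (!("R" %in% rates) || !identical(s_rates, seq_along(s_rates)))
    stop("vital_rate labels must be R plus contiguous S1..S(n-1); found: ",
         paste(sort(rates), collapse = ", "))
  build <- function(rate) {
    sub <- df[df$vital_rate == rate, ]
    m <- max(sub$covariate)
    w <- matrix(NA_real_, T, m)
    w[cbind(sub$cohort, sub$covariate)] <- sub$value
    if (anyNA(w)) {
      miss <- which(is.na(w), arr.ind = TRUE)
      stop("missing covariate cells for ", rate, ": cohort ",
           paste(unique(miss[, 1]), collapse = ","),
           " (no imputation is performed)")
    }
    cbind(1, w)
  }
  covariate_set(w_R = build("R"),
                w_S = lapply(paste0("S", s_rates), build))
}

#' Write vital-rate covariates
#'
#' Inverse of [read_covariates()].
#'
#' @param cov A [covariate_set()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_covariates <- function(cov, path) {
  long <- function(w, rate) {
    w <- w[, -1L, drop = FALSE]
    if (ncol(w) == 0L) return(NULL)
    data.frame(cohort = rep(seq_len(nrow(w)), ncol(w)),
               vital_rate = rate,
               covariate = rep(seq_len(ncol(w)), each = nrow(w)),
               value = as.vector(w))
  }
  df <- rbind(long(cov$w_R, "R"),
              do.call(rbind, lapply(seq_along(cov$w_S), function(i)
                long(cov$w_S[[i]], paste0("S", i)))))
  utils::write.csv(format(df, digits = 15, scientific = FALSE, trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Assemble a dataset from observation and covariate pieces
#'
#' @param obs A partial dataset from [read_observations()].
#' @param cov A [covariate_set()] (e.g. from [read_covariates()]).
#' @return An [ssm_dataset()].
#' @export
as_dataset <- function(obs, cov) {
  ssm_dataset(obs$Y, obs$sigma_o, cov, obs$survey_of_stage,
              obs$Y_init, obs$sigma_o_init)
}

#' Write a fit summary to plain-text files
#'
#' Emits a parameter table (parameter, estimate, SE, fixed flag) as CSV and
#' a JSON summary (log-likelihood, parameter count, observation count,
#' AICc, convergence flags).
#'
#' @param fit An [fit_mle()] result.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_fit <- function(fit, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tab <- summary_table(fit)
  tab$fixed <- FALSE
  fx <- list()
  if (length(fit$fix_psi))
    fx <- c(fx, list(data.frame(
      parameter = paste0("log_psi_", names(fit$fix_psi)),
      estimate = log(unname(fit$fix_psi)), se = NA_real_, fixed = TRUE)))
  if (!is.null(fit$fix_log_N_init))
    fx <- c(fx, list(data.frame(parameter = "log_N_init",
                                estimate = fit$fix_log_N_init,
                                se = NA_real_, fixed = TRUE)))
  if (length(fx)) tab <- rbind(tab, do.call(rbind, fx))
  utils::write.csv(tab, file.path(dir, "parameters.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(loglik = fit$loglik, k = length(fit$par), n_obs = fit$n_obs,
         aicc = tryCatch(aicc(fit), error = function(e) NA_real_),
         converged = fit$converged, hessian_pd = fit$hessian_pd),
    file.path(dir, "fit.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
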