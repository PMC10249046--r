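#' Split-chain Gelman-Rubin statistic
#'
#' Each chain is split in half and the classical potential scale reduction
#' factor is computed across the resulting half-chains for every parameter:
#' `R-hat = sqrt(((n - 1)/n * W + B/n) / W)` with `W` the mean within-chain
#' variance and `B` the between-chain variance of the half-chain means.
#' Values near 1 indicate between-chain agreement; > 1.1 is the conventional
#' warning level.
#'
#' @param chains A `"chain_set"` from [sample_posterior()], or a 3-d array
#'   `iterations x chains x parameters`.
#' @param split Split chains in half first (default `TRUE`).
#' @return Named vector of R-hat values, one per parameter.
#' @export
gelman_rubin <- function(chains, split = TRUE) {
  draws <- if (inherits(chains, "chain_set")) chains$draws else chains
  stopifnot(length(dim(draws)) == 3L)
  n <- dim(draws)[1]
  if (n < 2L || (split && n < 4L))
    stop("Gelman-Rubin is undefined for chains this short")
  if (split) {
    h <- floor(n / 2)
    m0 <- dim(draws)[2]
    sp <- array(NA_real_, c(h, 2 * m0, dim(draws)[3]),
                dimnames = list(NULL, NULL, dimnames(draws)[[3]]))
    sp[, seq_len(m0), ] <- draws[seq_len(h), , , drop = FALSE]
    sp[, m0 + seq_len(m0), ] <- draws[(n - h + 1):n, , , drop = FALSE]
    draws <- sp
    n <- h
  }
  m <- dim(draws)[2]
  rhat <- apply(draws, 3, function(x) {
    mns <- colMeans(x)
    W <- mean(apply(x, 2, stats::var))
    B <- n * stats::var(mns)
    if (W == 0) return(if (B == 0) 1 else Inf)
    sqrt(((n - 1) / n * W + B / n) / W)
  })
  nm <- dimnames(if (inherits(chains, "chain_set")) chains$draws else
    chains)[[3]]
  if (!is.null(nm)) names(rhat) <- nm
  rhat
}

#' Marginal and pairwise posterior summaries
#'
#' Pools the chains and reports marginal means, SDs and quantiles per
#' parameter, plus Pearson correlations and 2-d kernel density contours for
#' requested parameter pairs (the contour levels enclose roughly 50% and 90%
#' of the posterior mass).
#'
#' @param chains A `"chain_set"` from [sample_posterior()].
#' @param pairs Optional list of length-2 character vectors of parameter
#'   names.
#' @param grid_n Grid size for the 2-d kernel density estimate.
#' @return A list with `marginals` (data.frame) and `pairs` (a list with
#'   `cor` and contour data per pair).
#' @export
joint_posterior_summary <- function(chains, pairs = NULL, grid_n = 50L) {
  stopifnot(inherits(chains, "chain_set"))
  d <- dim(chains$draws)
  pooled <- matrix(chains$draws, d[1] * d[2], d[3])
  colnames(pooled) <- chains$params
  q <- t(apply(pooled, 2, stats::quantile, c(0.025, 0.5, 0.975)))
  marginals <- data.frame(parameter = chains$params,
                          mean = colMeans(pooled),
                          sd = apply(pooled, 2, stats::sd),
                          q2.5 = q[, 1], median = q[, 2], q97.5 = q[, 3],
                          row.names = NULL)
  pair_out <- lapply(pairs, function(pp) {
    stopifnot(length(pp) == 2L, all(pp %in% chains$params))
    x <- pooled[, pp[1]]
    y <- pooled[, pp[2]]
    kd <- MASS::kde2d(x, y, n = grid_n)
    # density levels enclosing ~50% / ~90% of draws
    dens <- sort(as.vector(kd$z), decreasing = TRUE)
    cs <- cumsum(dens) / sum(dens)
    levels <- c(`50%` = dens[which(cs >= 0.5)[1]],
                `90%` = dens[which(cs >= 0.9)[1]])
    list(pair = pp, cor = stats::cor(x, y), kde = kd, levels = levels)
  })
  if (!is.null(pairs))
    names(pair_out) <- vapply(pairs, paste, "", collapse = ":")
  list(marginals = marginals, pairs = pair_out)
}

#' Export chains as a long-format table
#'
#' One row per (iteration, chain, parameter) draw, suitable for external
#' diagnostic tools.
#'
#' @param chains A `"chain_set"`.
#' @return A data.frame with columns `iteration`, `chain`, `parameter`,
#'   `value`.
#' @export
chains_to_table <- function(chains) {
  stopifnot(inherits(chains, "chain_set"))
  d <- dim(chains$draws)
  data.frame(
    iteration = rep(seq_len(d[1]), times = d[2] * d[3]),
    chain = rep(rep(seq_len(d[2]), each = d[1]), times = d[3]),
    parameter = rep(chains$params, each = d[1] * d[2]),
    value = as.vector(chains$draws))
}

#' @export
print.chain_set <- function(x, ...) {
  cat(sprintf(
    "chain_set: %d chains x %d iterations (%d burn-in discarded), %d parameters\n",
    x$n_chains, x$n_iter, x$burn_in, length(x$params)))
  rh <- tryCatch(gelman_rubin(x), error = function(e) NULL)
  if (!is.null(rh))
    cat(sprintf("  max split R-hat: %.3f (%s)\n", max(rh),
                names(rh)[which.max(rh)]))
  invisible(x)
}
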