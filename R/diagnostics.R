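#' Gelman-Rubin potential scale reduction factor
#'
#' Classic between/within-chain variance ratio for a single scalar parameter:
#' with `M` chains of `n` kept draws, `W` the mean within-chain variance and
#' `B/n` the variance of the chain means, the pooled variance estimate is
#' `V = (n-1)/n * W + B/n` and `Rhat = sqrt(V / W)`. With no between-chain
#' variance the statistic attains its floor `sqrt((n-1)/n)`; values near 1
#' indicate the chains are sampling the same distribution.
#'
#' @param draws Matrix of posterior draws, rows = iterations, columns = chains.
#' @return `Rhat` (scalar); `NA` with a warning for a single chain.
#' @export
gelman_rubin <- function(draws) {
  draws <- as.matrix(draws)
  if (ncol(draws) < 2L) {
    warning("Gelman-Rubin diagnostic undefined for a single chain")
    return(NA_real_)
  }
  n <- nrow(draws)
  W <- mean(apply(draws, 2, stats::var))
  B_over_n <- stats::var(colMeans(draws))
  V <- (n - 1) / n * W + B_over_n
  if (W == 0) return(if (B_over_n == 0) 1 else Inf)
  sqrt(V / W)
}

#' Effective sample size of MCMC draws
#'
#' Estimates the integrated autocorrelation time from within-chain
#' autocorrelations averaged across chains, truncated at the first
#' non-positive even-odd pair sum (Geyer's initial positive sequence),
#' and returns `N / tau` where `N` is the total kept draw count.
#'
#' @param draws Matrix of draws, rows = iterations, columns = chains.
#' @return Estimated effective number of independent draws.
#' @export
effective_size <- function(draws) {
  draws <- as.matrix(draws)
  n <- nrow(draws)
  M <- ncol(draws)
  max_lag <- min(n - 1L, 2000L)
  rho <- rowMeans(vapply(seq_len(M), function(j) {
    a <- stats::acf(draws[, j], lag.max = max_lag, plot = FALSE,
                    demean = TRUE)$acf[-1]
    as.numeric(a)
  }, numeric(max_lag)))
  tau <- 1
  k <- 1L
  while (k + 1L <= max_lag) {
    pair <- rho[k] + rho[k + 1L]
    if (!is.finite(pair) || pair <= 0) break
    tau <- tau + 2 * pair
    k <- k + 2L
  }
  max(1, (n * M) / tau)
}

#' Monte-Carlo standard error of a posterior mean
#'
#' `sd(draws) / sqrt(effective_size(draws))`.
#'
#' @param draws Matrix of draws, rows = iterations, columns = chains.
#' @return Scalar Monte-Carlo standard error.
#' @export
mcse_mean <- function(draws) {
  stats::sd(as.numeric(draws)) / sqrt(effective_size(draws))
}
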