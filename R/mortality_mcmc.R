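#' MCMC settings
#'
#' Defaults follow the analysis this pipeline reproduces: three unthinned
#' chains of 20,000 iterations with the first 5,000 discarded as burn-in,
#' leaving 45,000 kept draws (three 15,000-draw chains).
#'
#' @param n_chains Number of chains (>= 2 for convergence diagnostics).
#' @param iterations_per_chain Total iterations per chain.
#' @param burn_in Iterations discarded from the start of each chain.
#' @param seed Integer seed; chains are independently seeded from it.
#' @return An object of class `mcmc_config`.
#' @export
mcmc_config <- function(n_chains = 3L, iterations_per_chain = 20000L,
                        burn_in = 5000L, seed = 1L) {
  if (burn_in >= iterations_per_chain) {
    stop("burn_in must be smaller than iterations_per_chain", call. = FALSE)
  }
  structure(list(n_chains = as.integer(n_chains),
                 iterations_per_chain = as.integer(iterations_per_chain),
                 burn_in = as.integer(burn_in),
                 thinning = 1L,
                 seed = as.integer(seed)),
            class = "mcmc_config")
}

#' Estimate per-cell drought-window mortality with death-date uncertainty
#'
#' Fits a saturated logistic (cell-means) mortality model: one fractional
#' mortality \eqn{m_{t,i}} per (taxonomic group t, height class i) cell,
#' with each dead tree's membership in the drought window treated as a latent
#' indicator. The data per cell are the trees alive at the survey
#' (`status = "live"`) and the standing dead trees, each dead tree j carrying
#' a prior probability `q_j` (from the gamma death-dating models) that it died
#' within the window rather than before it.
#'
#' Sampler (Metropolis-within-Gibbs, derived from the cell's complete-data
#' likelihood): given the current m, each dead tree's indicator is resampled
#' from its exact conditional
#' \deqn{P(z_j = 1 \mid m, q_j) = q_j m / (q_j m + (1 - q_j)),}
#' because a window death contributes \eqn{q_j m} (the tree was alive at the
#' window start and died) whereas a pre-window death contributes
#' \eqn{(1-q_j)} and drops out of the start-of-window population entirely.
#' Conditional on z, the cell's start-of-window population is
#' `living + sum(z)` and its window deaths `sum(z)`, giving a binomial
#' likelihood for m; the cell's logit-mortality is then updated by random-walk
#' Metropolis (step size adapted toward 44% acceptance during burn-in and
#' frozen afterwards). The prior on m is uniform on (0, 1) — diffuse and
#' uninformative — implemented on the logit scale with the Jacobian, so with
#' all q in {0, 1} the posterior is exactly Beta(deaths + 1, living + 1).
#' Resampling z every iteration propagates death-date uncertainty into the
#' credible intervals. There is no plot term: cells pool trees across plots.
#'
#' @param trees Tibble with one row per tree: `group`, `height_class`,
#'   `status` (`"live"`/`"dead"`), and `q` (dead trees only; `NA` for living).
#' @param cfg An [mcmc_config()].
#' @param cells Optional tibble (`group`, `height_class`) fixing the cell set
#'   and order; defaults to all combinations present in `trees`. Cells with
#'   no trees are skipped with a warning.
#' @return A `mortality_fit`: list with `cells` (tibble: `group`,
#'   `height_class`, `n_live`, `n_dead`, `sum_q`) and `draws` (list of
#'   kept-draw matrices of m, rows = iterations, columns = chains, one per
#'   cell), plus the config.
#' @export
fit_mortality <- function(trees, cfg = mcmc_config(), cells = NULL) {
  stopifnot(all(c("group", "height_class", "status", "q") %in% names(trees)))
  dead <- trees$status == "dead"
  if (any(is.na(trees$q[dead]))) {
    stop("every dead tree needs a window probability q", call. = FALSE)
  }
  if (any(trees$q[dead] < 0 | trees$q[dead] > 1, na.rm = TRUE)) {
    stop("q outside [0, 1]", call. = FALSE)
  }
  if (is.null(cells)) {
    cells <- dplyr::distinct(trees, .data$group, .data$height_class) |>
      dplyr::arrange(.data$group, .data$height_class)
  }
  keep <- logical(nrow(cells))
  draws <- vector("list", nrow(cells))
  info <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    sel <- trees$group == cells$group[i] &
      trees$height_class == cells$height_class[i]
    n_live <- sum(sel & !dead)
    q <- trees$q[sel & dead]
    if (n_live + length(q) == 0L) {
      warning("cell (", cells$group[i], ", ", cells$height_class[i],
              ") has no trees; skipped")
      next
    }
    keep[i] <- TRUE
    draws[[i]] <- sample_mortality_cell(n_live, q, cfg,
                                        cell_seed = cfg$seed + 104729L * i)
    info[[i]] <- tibble::tibble(group = cells$group[i],
                                height_class = cells$height_class[i],
                                n_live = n_live, n_dead = length(q),
                                sum_q = sum(q))
  }
  structure(list(cells = dplyr::bind_rows(info[keep]),
                 draws = draws[keep], config = cfg),
            class = "mortality_fit")
}

# One cell's sampler. Returns a (kept iterations) x (chains) matrix of m.
sample_mortality_cell <- function(n_live, q, cfg, cell_seed = cfg$seed) {
  # indicators with q exactly 0 or 1 never flip; only interior q are resampled
  k_fixed <- sum(q == 1)
  q_free <- q[q > 0 & q < 1]
  n_free <- length(q_free)
  kept <- cfg$iterations_per_chain - cfg$burn_in
  out <- matrix(NA_real_, kept, cfg$n_chains)
  for (ch in seq_len(cfg$n_chains)) {
    withr::local_seed(cell_seed + 15485863L * ch)
    k0 <- k_fixed + sum(q_free)
    theta <- stats::qlogis((k0 + 1) / (n_live + k_fixed + n_free + 2)) +
      stats::rnorm(1, 0, 0.5)
    step <- 0.5
    m <- stats::plogis(theta)
    lp <- NA_real_  # depends on k, recomputed each iteration
    for (it in seq_len(cfg$iterations_per_chain)) {
      # Gibbs update of latent window indicators given m
      k <- k_fixed
      if (n_free > 0) {
        p_z <- q_free * m / (q_free * m + (1 - q_free))
        k <- k + sum(stats::runif(n_free) < p_z)
      }
      # Metropolis update of logit m given k; uniform prior on m gives
      # target (k+1) log m + (n_live+1) log(1-m) on the logit scale
      lp <- (k + 1) * stats::plogis(theta, log.p = TRUE) +
        (n_live + 1) * stats::plogis(-theta, log.p = TRUE)
      theta_p <- theta + step * stats::rnorm(1)
      lp_p <- (k + 1) * stats::plogis(theta_p, log.p = TRUE) +
        (n_live + 1) * stats::plogis(-theta_p, log.p = TRUE)
      acc <- min(1, exp(lp_p - lp))
      if (stats::runif(1) < acc) theta <- theta_p
      m <- stats::plogis(theta)
      if (it <= cfg$burn_in) {
        step <- exp(log(step) + (acc - 0.44) / it^0.6)
      } else {
        out[it - cfg$burn_in, ch] <- m
      }
    }
  }
  out
}

#' Posterior summaries per mortality cell
#'
#' Pools kept draws across chains for the mean and central 95% credible
#' interval, and reports the Gelman-Rubin statistic and effective draw count
#' per cell.
#'
#' @param fit A `mortality_fit` from [fit_mortality()].
#' @return Tibble: `group`, `height_class`, `n_live`, `n_dead`, `mean`,
#'   `lo95`, `hi95`, `rhat`, `n_eff`.
#' @export
summarize_mortality <- function(fit) {
  stopifnot(inherits(fit, "mortality_fit"))
  if (fit$config$n_chains < 2L) {
    warning("fewer than 2 chains: Gelman-Rubin diagnostic unavailable")
  }
  rows <- lapply(seq_along(fit$draws), function(i) {
    d <- fit$draws[[i]]
    pooled <- as.numeric(d)
    qs <- stats::quantile(pooled, c(0.025, 0.975), names = FALSE)
    tibble::tibble(
      mean = mean(pooled), lo95 = qs[1], hi95 = qs[2],
      rhat = if (ncol(d) >= 2) gelman_rubin(d) else NA_real_,
      n_eff = effective_size(d)
    )
  })
  dplyr::bind_cols(fit$cells, dplyr::bind_rows(rows))
}

#' Back-calculate start-of-window populations and deaths
#'
#' Inverts the survivorship relation: with `n_2016` living trees recorded at
#' the survey and fractional window mortality `m`, the number alive at the
#' window start is `n_2013 = n_2016 / (1 - m)` and the window deaths are
#' `d = n_2013 - n_2016`. Values are real, not rounded: the downstream
#' decomposition works with proportions, and by construction `d / n_2013 = m`
#' exactly.
#'
#' @param n_2016 Living trees at the survey (vectorized).
#' @param m Fractional mortality in `[0, 1)` (vectorized).
#' @return Tibble: `n_2013`, `d`.
#' @export
back_calculate <- function(n_2016, m) {
  if (any(m < 0 | m >= 1)) stop("m must lie in [0, 1)", call. = FALSE)
  if (any(n_2016 < 0)) stop("n_2016 must be non-negative", call. = FALSE)
  n_2013 <- n_2016 / (1 - m)
  tibble::tibble(n_2013 = n_2013, d = n_2013 - n_2016)
}
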