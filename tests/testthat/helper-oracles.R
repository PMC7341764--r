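# Shared fixtures and independent oracles for the test suite.

# Tiny single-group config used where cell structure does not matter.
mini_config <- function(mortality, n_plots = 100, trees_per_plot = 100,
                        bdf = 0, seed = 11L, scale = 0.3) {
  mm <- matrix(mortality, nrow = 1, ncol = 3)
  colnames(mm) <- height_class_levels()
  rownames(mm) <- "angiosperm"
  comp <- matrix(1, nrow = 3, ncol = 1)
  colnames(comp) <- "angiosperm"
  sim_config(
    n_plots = n_plots, trees_per_plot_mean = trees_per_plot,
    group_names = "angiosperm",
    species_per_group = list(angiosperm = "Quercus kelloggii"),
    height_class_probs = c(0.4, 0.4, 0.2),
    composition_by_height = comp,
    mortality_by_cell = mm,
    dbh_distribution = default_dbh_distribution()["Quercus kelloggii"],
    retention_model = list(cutpoints = c(1, 2, 3, 7), scale = scale),
    background_dead_fraction = bdf,
    seed = seed
  )
}

# Conjugate oracle for cells whose window indicators are all certain:
# uniform prior + binomial likelihood => Beta(k + 1, L + 1).
beta_oracle <- function(k, L) {
  list(mean = (k + 1) / (k + L + 2),
       lo95 = qbeta(0.025, k + 1, L + 1),
       hi95 = qbeta(0.975, k + 1, L + 1),
       dens = function(x) dbeta(x, k + 1, L + 1))
}

# Exact marginalization over the latent window indicators: posterior density
# on m proportional to (1 - m)^L * prod_j (q_j m + 1 - q_j), uniform prior.
# Evaluated on a fine grid; returns mean and central 95% interval.
marginal_oracle <- function(L, q, n_grid = 40001) {
  grid <- seq(1e-7, 1 - 1e-7, length.out = n_grid)
  logd <- L * log1p(-grid)
  for (qq in q) logd <- logd + log(qq * grid + 1 - qq)
  d <- exp(logd - max(logd))
  d <- d / sum(d)
  cdf <- cumsum(d)
  list(mean = sum(grid * d),
       lo95 = grid[which.max(cdf >= 0.025)],
       hi95 = grid[which.max(cdf >= 0.975)],
       dens_grid = list(x = grid, y = d / (grid[2] - grid[1])))
}

# Monte-Carlo standard error of an estimated quantile: sqrt(p(1-p)/ess)
# divided by the target density at the quantile.
quantile_mcse <- function(p, ess, dens_at_q) {
  sqrt(p * (1 - p) / ess) / dens_at_q
}

# One synthetic mortality cell with exactly calibrated intermediate q.
# Per-tree generative model matching the sampler's likelihood: each of the
# n_2013 candidate trees is a pre-window snag with probability
# m*rho/(1 + m*rho) (so pre-window snags are bdf of expected dead), otherwise
# it enters the window population and dies with probability m. Dead trees
# emit one of three retention-like signals with cohort-specific frequencies;
# the assigned q solves q*m/(q*m + 1 - q) = P(window | signal), making the
# sampler's latent-indicator conditional exact at the true m.
calibrated_cell <- function(m, n_2013 = 500, bdf = 0.3,
                            f_win = c(0.70, 0.25, 0.05),
                            f_pre = c(0.05, 0.25, 0.70)) {
  rho <- bdf / (1 - bdf)
  p_pre <- m * rho / (1 + m * rho)
  u <- runif(n_2013)
  pre <- u < p_pre
  win <- !pre & (runif(n_2013) < m)
  live <- !pre & !win
  n_dead <- sum(pre | win)
  sig <- integer(n_2013)
  sig[win] <- sample.int(3L, sum(win), replace = TRUE, prob = f_win)
  sig[pre] <- sample.int(3L, sum(pre), replace = TRUE, prob = f_pre)
  # true P(window | dead, signal); m-free because the pre pool scales with m
  c_s <- f_win / (f_win + rho * f_pre)
  q_s <- c_s / (c_s + m * (1 - c_s))
  list(n_live = sum(live), q = q_s[sig[pre | win]],
       true_m = m, n_window_dead = sum(win))
}

# Random decomposition count tables for algebraic property tests.
random_count_table <- function(n_groups = 3, n_classes = 3) {
  tibble::tibble(
    height_class = rep(paste0("c", seq_len(n_classes)), each = n_groups),
    group = rep(paste0("g", seq_len(n_groups)), times = n_classes),
    n = runif(n_groups * n_classes, 1, 500)
  ) |>
    dplyr::mutate(d = runif(dplyr::n()) * n)
}
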