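test_that("species map encodes the calibration fallback rules", {
  expect_equal(map_calibration_group("Abies magnifica"), "Abies concolor")
  expect_equal(map_calibration_group("Torreya californica"), "Abies concolor")
  expect_equal(map_calibration_group("Quercus kelloggii"), "Quercus kelloggii")
  expect_equal(map_calibration_group("Pinus jeffreyi"),
               "Pinus ponderosa + Pinus lambertiana")
  expect_equal(map_calibration_group(c("Cornus nuttallii", "Abies concolor")),
               c("Quercus kelloggii", "Abies concolor"))
  expect_error(map_calibration_group("Sequoiadendron giganteum"),
               "Sequoiadendron")
})

test_that("gamma fits recover known parameters (MLE oracle, Bayes agreement)", {
  set.seed(21)
  x <- rgamma(10000, shape = 2, rate = 0.5)
  mle <- fitdistrplus::fitdist(x, "gamma", method = "mle")$estimate
  expect_lt(abs(mle[["shape"]] - 2) / 2, 0.05)
  expect_lt(abs(mle[["rate"]] - 0.5) / 0.5, 0.05)
  bs <- snagmort:::gamma_posterior(x, mcmc_config(iterations_per_chain = 6000,
                                                  burn_in = 2000, seed = 5))
  expect_lt(abs(mean(bs$shape) - mle[["shape"]]) / mle[["shape"]], 0.05)
  expect_lt(abs(mean(bs$rate) - mle[["rate"]]) / mle[["rate"]], 0.05)
  expect_lt(bs$rhat, 1.1)
})

test_that("cell structure: pooling fallback, small-cell flags, degenerate errors", {
  set.seed(8)
  survey <- 2016
  calib <- tibble::tibble(
    species = "Quercus kelloggii",
    death_year = survey - rpois(120, 4),
    survey_year = survey,
    retention_class = rep(c("R1", "R2"), times = c(118, 2))
  )
  gm <- fit_gamma_death_model(calib, method = "mle")
  fits <- gm$fits
  # R2 has < 3 records: flagged unusable, lookup falls back to the pooled fit
  expect_false(fits$usable[!is.na(fits$retention_class) &
                             fits$retention_class == "R2"])
  cell <- snagmort:::lookup_gamma_cell(gm, "Quercus kelloggii", "R2")
  expect_true(cell$pooled)
  pooled <- fits[fits$pooled, ]
  expect_equal(cell$shape, pooled$shape)
  # all-identical times cannot be fitted by MLE
  degen <- calib
  degen$death_year <- survey - 3L
  expect_error(fit_gamma_death_model(degen, method = "mle"), "degenerate")
})

test_that("window probability follows the gamma CDF at T* years", {
  mk_model <- function(shape, rate) {
    structure(list(
      fits = tibble::tibble(group = "Quercus kelloggii", retention_class = "R1",
                            shape = shape, rate = rate, n = 100, method = "mle",
                            pooled = FALSE, usable = TRUE, rhat = NA_real_),
      draws = list(), method = "mle"), class = "gamma_death_model")
  }
  tree <- tibble::tibble(tree_id = "T1", species = "Quercus kelloggii",
                         retention_class = "R1")
  # survey 2016, window 2014-2016 => T* = 3 years
  # shape 1 is exponential: q = 1 - exp(-3 r)
  for (r in c(0.2, 1, 3)) {
    q <- prob_death_in_window(mk_model(1, r), tree, 2016)$q
    expect_equal(q, 1 - exp(-3 * r), tolerance = 1e-12)
  }
  # CDF saturation: all mass below / above T*
  expect_gt(prob_death_in_window(mk_model(2, 200), tree, 2016)$q, 1 - 1e-12)
  expect_lt(prob_death_in_window(mk_model(200, 1), tree, 2016)$q, 1e-12)
  # q decreases as the mean time since death grows (shape fixed)
  qs <- vapply(c(2, 1, 0.5, 0.25, 0.125),
               function(r) prob_death_in_window(mk_model(2, r), tree, 2016)$q,
               numeric(1))
  expect_true(all(diff(qs) < 0))
  # living trees are a contract violation
  expect_error(prob_death_in_window(mk_model(1, 1),
                                    dplyr::mutate(tree, status = "live"), 2016),
               "dead")
})

test_that("inferred q separates death cohorts under a deterministic retention model", {
  # step model with a cutpoint at the window boundary; each class spans
  # several death cohorts so the gamma fits are non-degenerate
  cfg <- sim_config(retention_model = list(cutpoints = c(3, 7), scale = 0),
                    seed = 14)
  calib <- generate_calibration(cfg, 2000)
  gm <- fit_gamma_death_model(calib, method = "mle")
  inv <- generate_inventory(cfg)
  dead <- inv$trees[inv$trees$status == "dead", ]
  q <- prob_death_in_window(gm, dead, cfg$survey_year, cfg$drought_window)$q
  truth <- dead$true_death_year >= 2014
  # rank-based AUC of q as a classifier of window membership
  r <- rank(q)
  auc <- (sum(r[truth]) - sum(truth) * (sum(truth) + 1) / 2) /
    (sum(truth) * sum(!truth))
  expect_gt(auc, 0.95)
})

test_that("Bayes and MLE window probabilities agree at large calibration n", {
  set.seed(31)
  x <- rgamma(5000, shape = 2.5, rate = 0.8)
  mle <- fitdistrplus::fitdist(x, "gamma", method = "mle")$estimate
  q_mle <- pgamma(3, shape = mle[["shape"]], rate = mle[["rate"]])
  bs <- snagmort:::gamma_posterior(x, mcmc_config(iterations_per_chain = 6000,
                                                  burn_in = 2000, seed = 6))
  q_bayes <- mean(pgamma(3, shape = bs$shape, rate = bs$rate))
  expect_lt(abs(q_bayes - q_mle), 0.02)
})
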