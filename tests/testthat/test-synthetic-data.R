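test_that("identical configs give identical inventories and calibration sets", {
  cfg <- sim_config(n_plots = 15, seed = 77)
  a <- generate_inventory(cfg)
  b <- generate_inventory(cfg)
  expect_identical(a$trees, b$trees)
  expect_identical(a$truth$cells, b$truth$cells)
  expect_identical(generate_calibration(cfg, 200), generate_calibration(cfg, 200))
  # a different seed changes the draw
  cfg2 <- sim_config(n_plots = 15, seed = 78)
  expect_false(identical(generate_inventory(cfg2)$trees, a$trees))
})

test_that("zero mortality produces no drought-window deaths", {
  cfg <- mini_config(mortality = 0, n_plots = 30, trees_per_plot = 50)
  inv <- generate_inventory(cfg)
  dy <- inv$trees$true_death_year
  expect_false(any(!is.na(dy) & dy >= 2014 & dy <= 2016))
  expect_equal(sum(inv$truth$cells$true_window_deaths), 0)
})

test_that("realized window mortality matches the cell probability (binomial oracle)", {
  cfg <- mini_config(mortality = 0.5, n_plots = 100, trees_per_plot = 100)
  inv <- generate_inventory(cfg)
  cells <- inv$truth$cells
  n <- sum(cells$true_n_start)
  expect_gt(n, 5000)
  frac <- sum(cells$true_window_deaths) / n
  se <- sqrt(0.5 * 0.5 / n)
  expect_lt(abs(frac - 0.5), 3 * se)
  # per-cell law of large numbers at a lower rate
  cfg2 <- mini_config(mortality = c(0.1, 0.3, 0.6), n_plots = 200,
                      trees_per_plot = 500, seed = 12)
  cells2 <- generate_inventory(cfg2)$truth$cells
  for (i in seq_len(nrow(cells2))) {
    p <- cells2$true_mortality[i]
    se_i <- sqrt(p * (1 - p) / cells2$true_n_start[i])
    expect_lt(abs(cells2$true_window_deaths[i] / cells2$true_n_start[i] - p),
              3 * se_i)
  }
})

test_that("default inventory emulates the study design", {
  inv <- generate_inventory(sim_config(seed = 101))
  n <- nrow(inv$trees)
  expect_lt(abs(n - 5855) / 5855, 0.20)
  # composition pattern: angiosperm share falls with height, Pinus share rises
  shares <- inv$truth$cells |>
    dplyr::group_by(height_class) |>
    dplyr::mutate(share = true_n_start / sum(true_n_start)) |>
    dplyr::ungroup()
  get <- function(g, h) shares$share[shares$group == g & shares$height_class == h]
  expect_gt(get("angiosperm", "5-15m"), get("angiosperm", "15-30m"))
  expect_gt(get("angiosperm", "15-30m"), get("angiosperm", ">30m"))
  expect_lt(get("pinus", "5-15m"), get("pinus", "15-30m"))
  expect_lt(get("pinus", "15-30m"), get("pinus", ">30m"))
  # record invariants
  trees <- inv$trees
  expect_true(all(trees$dbh_class %% 5 == 0 & trees$dbh_class >= 0))
  expect_true(all(is.na(trees$retention_class) == (trees$status == "live")))
  expect_true(all(trees$true_death_year <= 2016, na.rm = TRUE))
  # roughly 30% of snags pre-date the window (background_dead_fraction)
  dead <- trees[trees$status == "dead", ]
  expect_lt(abs(mean(dead$true_death_year < 2014) - 0.3), 0.05)
})

test_that("deterministic retention separates death cohorts at the cutpoints", {
  cfg <- sim_config(retention_model = list(cutpoints = c(1, 2, 3, 7), scale = 0),
                    seed = 33)
  # step model: class = 1 + #(cutpoints < time since death), exactly
  expect_equal(as.character(draw_retention(c(0.5, 1.5, 2.5, 3.5, 10.5),
                                           cfg$retention_model)),
               c("R1", "R2", "R3", "R4", "R5"))
  inv <- generate_inventory(cfg)
  dead <- inv$trees[inv$trees$status == "dead", ]
  in_window <- dead$true_death_year >= 2014
  # window deaths (time since death <= 2.5) occupy R1-R3; older snags R4-R5
  expect_true(all(dead$retention_class[in_window] %in% c("R1", "R2", "R3")))
  expect_true(all(dead$retention_class[!in_window] %in% c("R4", "R5")))
})

test_that("calibration records respect the survey calendar", {
  cfg <- sim_config(seed = 3)
  calib <- generate_calibration(cfg, 2297)
  expect_equal(nrow(calib), 2297)
  expect_true(all(calib$death_year <= calib$survey_year))
  one <- generate_calibration(cfg, 1)
  expect_equal(nrow(one), 1)
  expect_error(generate_calibration(cfg, 0), "positive")
})

test_that("configuration validation catches inconsistent inputs", {
  expect_error(sim_config(composition_by_height = matrix(0.5, 3, 2)),
               "3 x 3")
  bad_comp <- default_composition()
  bad_comp[1, ] <- c(0.5, 0.4, 0.2)
  expect_error(sim_config(composition_by_height = bad_comp), "sum")
  bad_m <- default_mortality()
  bad_m[2, 2] <- 1.4
  expect_error(sim_config(mortality_by_cell = bad_m), "\\[0, 1\\]")
  expect_error(sim_config(drought_window = c(2015, 2017)), "survey_year")
})

test_that("sim configs round-trip through YAML", {
  cfg <- sim_config(seed = 9, trees_per_plot_mean = 42)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_sim_config(cfg, path)
  cfg2 <- read_sim_config(path)
  expect_equal(cfg2$trees_per_plot_mean, 42)
  expect_equal(unname(cfg2$mortality_by_cell), unname(cfg$mortality_by_cell))
  expect_equal(unname(cfg2$composition_by_height),
               unname(cfg$composition_by_height))
  expect_identical(generate_inventory(cfg2)$trees, generate_inventory(cfg)$trees)
})
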