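test_that("pooled mortality: count form equals the composition-weighted form", {
  expect_equal(pooled_mortality(100, 50), 0.5)
  # n = (100, 100), d = (10, 50): pooled 60/200, weighted 0.5*0.1 + 0.5*0.5
  expect_equal(pooled_mortality(c(100, 100), c(10, 50)), 0.3)
  expect_equal(sum(proportions(c(100, 100)) * c(0.1, 0.5)), 0.3)
  expect_equal(pooled_mortality(c(5, 9), c(5, 9)), 1)
  expect_error(pooled_mortality(c(0, 0), c(0, 0)), "no trees")
  expect_error(pooled_mortality(10, 11), "d <= n")
  # property: Eq-1-style pooling == Eq-5-style weighting, random tables
  set.seed(6)
  for (i in 1:200) {
    tab <- decomposition_table(random_count_table())
    by_class <- split(tab, tab$height_class)
    for (cl in by_class) {
      expect_equal(pooled_mortality(cl$n, cl$d), sum(cl$m * cl$p),
                   tolerance = 1e-12)
      # convexity: pooled M inside the group mortality range
      expect_gte(cl$M[1], min(cl$m) - 1e-12)
      expect_lte(cl$M[1], max(cl$m) + 1e-12)
    }
  }
})

test_that("proportions behave as relative abundances", {
  expect_equal(unname(proportions(c(3, 3, 3))), rep(1 / 3, 3))
  expect_equal(unname(proportions(c(90, 10))), c(0.9, 0.1))
  expect_error(proportions(c(-1, 2)), "negative")
  # start-of-window proportions differ from all-standing-tree proportions
  # when group mortalities differ: 2 groups, equal survivors, unequal deaths
  n2016 <- c(80, 80)
  m <- c(0.5, 0.1)
  bc <- back_calculate(n2016, m)
  p_2013 <- proportions(bc$n_2013)
  p_all <- proportions(n2016 + bc$d)  # living + window-dead standing trees
  expect_equal(unname(p_2013), unname(p_all), tolerance = 1e-12)
  # but against the *living* composition they differ
  expect_gt(abs(p_2013[1] - proportions(n2016)[1]), 0.05)
})

test_that("composition standardization: identity, invariance, reversal arithmetic", {
  set.seed(7)
  for (i in 1:50) {
    tab <- decomposition_table(random_count_table())
    groups <- unique(tab$group)
    # reference = each class's own composition reproduces observed M
    for (cl in split(tab, tab$height_class)) {
      own <- setNames(cl$p, cl$group)
      expect_equal(standardize_composition(cl, own)$M_star, cl$M[1],
                   tolerance = 1e-12)
    }
    # equal mortalities within a class make M* composition-free
    tab_eq <- tab |> dplyr::group_by(height_class) |>
      dplyr::mutate(m = m[1], d = m * n) |> dplyr::ungroup() |>
      dplyr::select(height_class, group, n, d) |> decomposition_table()
    ref <- setNames(proportions(runif(length(groups), 1, 10)), groups)
    ms <- standardize_composition(tab_eq, ref)
    cls <- split(tab_eq, tab_eq$height_class)
    for (h in names(cls)) {
      expect_equal(ms$M_star[ms$height_class == h], cls[[h]]$m[1],
                   tolerance = 1e-12)
    }
  }
  tab <- decomposition_table(random_count_table())
  expect_error(standardize_composition(tab, c(a = 0.5, b = 0.5)), "groups")
  expect_error(standardize_composition(
    tab, setNames(c(0.5, 0.4, 0.2), unique(tab$group))), "sum to 1")
})

test_that("constant-group-mortality standardization isolates the focal trend", {
  # focal group with constant mortality: replacement by that value is identity
  df <- tibble::tibble(
    height_class = rep(c("c1", "c2"), each = 2),
    group = rep(c("A", "B"), 2),
    n = c(90, 10, 50, 50),
    d = c(9, 3, 5, 15)  # m_B = 0.3 in both classes
  )
  tab <- decomposition_table(df)
  out <- standardize_group_mortality(tab, "B", 0.3)
  expect_equal(out$M_star[match(c("c1", "c2"), out$height_class)],
               unique(tab[, c("height_class", "M")])$M, tolerance = 1e-12)
  # zero-weight group: any replacement value leaves M unchanged
  df0 <- df
  df0$n[df0$group == "B"] <- 0
  df0$d[df0$group == "B"] <- 0
  tab0 <- decomposition_table(df0)
  for (pm in c(0, 0.5, 1)) {
    out0 <- standardize_group_mortality(tab0, "B", pm)
    expect_equal(out0$M_star[match(c("c1", "c2"), out0$height_class)],
                 unique(tab0[, c("height_class", "M")])$M, tolerance = 1e-12)
  }
  # flattening a rising focal trend attenuates the pooled height trend:
  # hand evaluation with p_B = 0.3, m_A = (0.2, 0.2), m_B: (0.1, 0.7) -> 0.4
  df2 <- tibble::tibble(
    height_class = rep(c("c1", "c2"), each = 2),
    group = rep(c("A", "B"), 2),
    n = c(700, 300, 700, 300),
    d = c(140, 30, 140, 210)
  )
  tab2 <- decomposition_table(df2)
  out2 <- standardize_group_mortality(tab2, "B", 0.4)
  expect_equal(out2$M_star[match(c("c1", "c2"), out2$height_class)],
               c(0.7 * 0.2 + 0.3 * 0.4, 0.7 * 0.2 + 0.3 * 0.4),
               tolerance = 1e-12)
  expect_error(standardize_group_mortality(tab2, "Z", 0.1), "unknown group")
})

test_that("two-group scenario arithmetic matches hand evaluation", {
  tab <- scenario_table(p_b = c(0.1, 0.9), m_a = c(0.30, 0.20),
                        m_b = c(0.60, 0.50))
  M <- unique(tab[, c("height_class", "M")])
  expect_equal(M$M[match(c("class1", "class2"), M$height_class)], c(0.33, 0.47),
               tolerance = 1e-12)
  # pooled-count route agrees: per class, M = total d / total n
  for (cl in split(tab, tab$height_class)) {
    expect_equal(cl$M[1], sum(cl$d) / sum(cl$n), tolerance = 1e-12)
  }
  expect_error(scenario_table(p_b = c(0.1, 1.2), m_a = c(0.1, 0.1),
                              m_b = c(0.1, 0.1)), "\\[0, 1\\]")
})

test_that("shared-decline preset shows a composition-driven Simpson reversal", {
  tab <- scenario_preset("shared-decline")
  ord <- match(height_class_levels(), unique(tab$height_class))
  m_by_group <- split(tab, tab$group)
  for (g in m_by_group) expect_true(all(diff(g$m[ord]) < 0))
  M <- unique(tab[, c("height_class", "M")])$M
  expect_true(all(diff(M[ord]) > 0))
  rep <- detect_simpson_reversal(tab)
  expect_true(rep$reversal)
  expect_equal(rep$pooled_trend, "increasing")
  expect_false(rep$opposing_trends)
})

test_that("opposing-trends preset is flagged as opposing, not a reversal", {
  tab <- scenario_preset("opposing-trends")
  rep <- detect_simpson_reversal(tab)
  expect_false(rep$reversal)
  expect_true(rep$opposing_trends)
  expect_equal(rep$pooled_trend, "increasing")
  trends <- setNames(rep$group_trends$trend, rep$group_trends$group)
  expect_equal(unname(trends["C"]), "decreasing")
  expect_equal(unname(trends["D"]), "increasing")
})

test_that("reversal detection respects height order regardless of row order", {
  tab <- scenario_preset("shared-decline")
  scrambled <- tab[order(tab$height_class), ]  # alphabetical: 15-30m first
  rep_s <- detect_simpson_reversal(scrambled)
  expect_true(rep_s$reversal)
  expect_equal(rep_s$pooled_trend, "increasing")
  # explicit ordering for non-standard labels
  df <- tibble::tibble(
    height_class = rep(c("tall", "short"), each = 2),
    group = rep(c("A", "B"), 2),
    n = c(50, 50, 50, 50), d = c(10, 20, 5, 10)
  )
  rep_e <- detect_simpson_reversal(decomposition_table(df),
                                   class_order = c("short", "tall"))
  expect_equal(rep_e$pooled_trend, "increasing")
  expect_error(detect_simpson_reversal(decomposition_table(df),
                                       class_order = c("short", "mid")),
               "class_order")
})

test_that("concordant trends are not reversals and single classes error", {
  df <- tibble::tibble(
    height_class = rep(c("c1", "c2"), each = 2),
    group = rep(c("A", "B"), 2),
    n = c(50, 50, 50, 50), d = c(5, 10, 10, 20)
  )
  rep <- detect_simpson_reversal(decomposition_table(df))
  expect_false(rep$reversal)
  expect_false(rep$opposing_trends)
  one <- decomposition_table(df[df$height_class == "c1", ])
  expect_error(detect_simpson_reversal(one), "2 height classes")
})
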