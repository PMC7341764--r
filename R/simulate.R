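#' Draw snag retention classes from time since death
#'
#' Retention of foliage and fine twigs decays with time since death. The
#' generator uses an ordinal-logistic model on the time axis: a latent time
#' `u = t + logistic noise(scale)` is compared against the model's cutpoints,
#' and the class index is `1 + #(cutpoints < u)`. `scale = 0` collapses this
#' to a deterministic step function of time since death, which is useful for
#' tests that need perfect separation of death cohorts.
#'
#' @param time_since_death Numeric vector, years.
#' @param retention_model List with `cutpoints` and `scale` (see [sim_config()]).
#' @return Ordered factor `R1 < R2 < ...` with `length(cutpoints) + 1` levels;
#'   `R1` is the freshest (most retentive) class.
#' @export
draw_retention <- function(time_since_death, retention_model) {
  cp <- retention_model$cutpoints
  sc <- retention_model$scale
  n <- length(time_since_death)
  u <- if (sc > 0) stats::rlogis(n, location = time_since_death, scale = sc)
       else time_since_death
  idx <- 1L + rowSums(outer(u, cp, `>`))
  levs <- paste0("R", seq_len(length(cp) + 1L))
  factor(levs[idx], levels = levs, ordered = TRUE)
}

#' Generate a synthetic standing-tree inventory with known truth
#'
#' Simulates the survey the downstream analysis expects: standing trees
#' (living, or dead with a retention class) on randomly placed plots, with a
#' latent true death year per dead tree that inference never reads. Each tree
#' is generated directly in a height class (marginal `height_class_probs`),
#' assigned a taxonomic group from that class's composition, a species within
#' the group, and a 5-cm DBH class drawn from the species' truncated
#' log-normal DBH distribution restricted to the class's DBH range under the
#' species' allometry — so allometric class assignment recovers the generating
#' class. Trees alive at the start of the drought window die within it with
#' the cell's `mortality_by_cell` probability; additional pre-window snags are
#' added so that, in expectation, `background_dead_fraction` of standing dead
#' trees pre-date the window.
#'
#' @param config A [sim_config()].
#' @param allometry Named list of [allometry_params()] covering every species;
#'   defaults to [default_allometry()].
#' @return List with `trees` (one row per standing tree: `tree_id`, `plot_id`,
#'   `species`, `group`, `dbh_class`, `status`, `retention_class`,
#'   `true_death_year`) and `truth` (list: `cells`, a per group x height class
#'   tibble of true mortality, true start-of-window population and true window
#'   deaths; `height_class`, the per-tree generating class).
#' @export
generate_inventory <- function(config, allometry = NULL) {
  config <- validate_sim_config(config)
  if (is.null(allometry)) {
    allometry <- default_allometry(unlist(config$species_per_group, use.names = FALSE))
  }
  all_sp <- unlist(config$species_per_group, use.names = FALSE)
  missing_al <- setdiff(all_sp, names(allometry))
  if (length(missing_al) > 0) {
    stop("allometry missing species: ", paste(missing_al, collapse = ", "),
         call. = FALSE)
  }
  withr::local_seed(config$seed)

  groups <- config$group_names
  classes <- height_class_levels()
  thr <- threshold_table(allometry[all_sp])

  n_per_plot <- stats::rpois(config$n_plots, config$trees_per_plot_mean)
  n <- sum(n_per_plot)
  plot_id <- rep(sprintf("P%03d", seq_len(config$n_plots)), times = n_per_plot)

  hc_idx <- sample.int(3L, n, replace = TRUE, prob = config$height_class_probs)
  grp_idx <- integer(n)
  for (i in 1:3) {
    sel <- hc_idx == i
    grp_idx[sel] <- sample.int(length(groups), sum(sel), replace = TRUE,
                               prob = config$composition_by_height[i, ])
  }
  species <- character(n)
  for (gi in seq_along(groups)) {
    sel <- grp_idx == gi
    sp <- config$species_per_group[[groups[gi]]]
    species[sel] <- sample(sp, sum(sel), replace = TRUE)
  }

  dbh_class <- draw_dbh_classes(species, hc_idx, config, thr)

  # Vital status: pre-window snag, window death, or alive at survey.
  m_tree <- config$mortality_by_cell[cbind(grp_idx, hc_idx)]
  rho <- config$background_dead_fraction / (1 - config$background_dead_fraction)
  p_pre <- m_tree * rho / (1 + m_tree * rho)
  u <- stats::runif(n)
  pre_window <- u < p_pre
  window_dead <- !pre_window & (stats::runif(n) < m_tree)

  w1 <- config$drought_window[1]
  w2 <- config$drought_window[2]
  death_year <- rep(NA_integer_, n)
  death_year[window_dead] <- sample(w1:w2, sum(window_dead), replace = TRUE)
  death_year[pre_window] <- sample(seq(w1 - config$background_death_span, w1 - 1L),
                                   sum(pre_window), replace = TRUE)

  status <- ifelse(is.na(death_year), "live", "dead")
  tsd <- config$survey_year - death_year + 0.5
  retention <- rep(NA_character_, n)
  dead <- status == "dead"
  retention[dead] <- as.character(draw_retention(tsd[dead], config$retention_model))

  trees <- tibble::tibble(
    tree_id = sprintf("T%05d", seq_len(n)),
    plot_id = plot_id,
    species = species,
    group = groups[grp_idx],
    dbh_class = dbh_class,
    status = status,
    retention_class = retention,
    true_death_year = death_year
  )

  alive_start <- !pre_window  # in the start-of-window population
  cells <- tidyr::expand_grid(group = groups, height_class = classes) |>
    dplyr::rowwise() |>
    dplyr::mutate(
      true_mortality = config$mortality_by_cell[match(.data$group, groups),
                                                match(.data$height_class, classes)],
      true_n_start = sum(alive_start & grp_idx == match(.data$group, groups) &
                           hc_idx == match(.data$height_class, classes)),
      true_window_deaths = sum(window_dead & grp_idx == match(.data$group, groups) &
                                 hc_idx == match(.data$height_class, classes))
    ) |>
    dplyr::ungroup()

  truth <- list(
    cells = cells,
    height_class = tibble::tibble(tree_id = trees$tree_id,
                                  height_class = classes[hc_idx])
  )
  list(trees = trees, truth = truth)
}

# Sample 5-cm DBH classes consistent with each tree's generating height class:
# the species' log-normal, discretized to 5-cm bins and truncated to the DBH
# range the allometry maps onto that height class.
draw_dbh_classes <- function(species, hc_idx, config, thr) {
  n <- length(species)
  out <- numeric(n)
  key <- paste(species, hc_idx)
  for (k in unique(key)) {
    sel <- key == k
    sp <- species[which(sel)[1]]
    hi_class <- hc_idx[which(sel)[1]]
    row <- thr[thr$species == sp, ]
    lo <- c(row$dbh_at_5m, row$dbh_at_15m, row$dbh_at_30m)[hi_class]
    hi <- c(row$dbh_at_15m, row$dbh_at_30m, NA_real_)[hi_class]
    if (is.na(lo)) {
      stop("height class ", height_class_levels()[hi_class],
           " is unreachable for species ", sp, call. = FALSE)
    }
    d <- config$dbh_distribution[[sp]]
    if (is.na(hi)) {
      hi <- max(lo + 5, ceiling(stats::qlnorm(0.9999, d$meanlog, d$sdlog) / 5) * 5)
    }
    bins <- seq(lo, hi - 5, by = 5)
    pr <- stats::plnorm(bins + 5, d$meanlog, d$sdlog) -
      stats::plnorm(bins, d$meanlog, d$sdlog)
    if (sum(pr) <= 0) pr <- rep(1, length(bins))  # class deep in the tail
    out[sel] <- if (length(bins) == 1L) bins else
      sample(bins, sum(sel), replace = TRUE, prob = pr)
  }
  out
}

#' Generate death-date calibration records
#'
#' Emulates the reference sample of standing dead trees whose exact death
#' years are known from long-term plot records: each record carries a species,
#' a known death year and the retention class the tree showed at the survey,
#' drawn from the same retention model that generated the inventory's snags.
#' Death years are uniform over the `calibration_span` years up to the survey,
#' so every retention class is represented across a range of times since death.
#'
#' @param config A [sim_config()].
#' @param n_trees Number of calibration records (default 2297).
#' @param seed Optional seed; defaults to `config$seed + 1` so that inventory
#'   and calibration draws are independent but jointly reproducible.
#' @return Tibble: `species`, `death_year`, `survey_year`, `retention_class`.
#' @export
generate_calibration <- function(config, n_trees = 2297, seed = NULL) {
  config <- validate_sim_config(config)
  if (n_trees <= 0) stop("n_trees must be positive", call. = FALSE)
  withr::local_seed(if (is.null(seed)) config$seed + 1L else seed)
  all_sp <- unlist(config$species_per_group, use.names = FALSE)
  species <- sample(all_sp, n_trees, replace = TRUE)
  death_year <- sample(seq(config$survey_year - config$calibration_span,
                           config$survey_year),
                       n_trees, replace = TRUE)
  tsd <- config$survey_year - death_year + 0.5
  tibble::tibble(
    species = species,
    death_year = death_year,
    survey_year = config$survey_year,
    retention_class = as.character(draw_retention(tsd, config$retention_model))
  )
}
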