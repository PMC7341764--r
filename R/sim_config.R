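#' Configuration for the synthetic forest inventory
#'
#' Bundles every knob of the synthetic landscape: plot design, taxonomic
#' composition by height class, per-cell (group x height class) drought-window
#' mortality probabilities, DBH distributions, the snag retention model and
#' the survey calendar. The defaults emulate the study design the pipeline is
#' built for: 89 plots of ~66 standing trees at least 5 m tall (~5,900 total),
#' three taxonomic groups (angiosperms, non-*Pinus* conifers, *Pinus*) whose
#' relative abundances shift with height (angiosperms dominate the short
#' class and decline with height; *Pinus* is ~11% of trees overall but rises
#' to ~30% of the tallest class), and mortality probabilities inside the
#' observed ranges: low and declining for angiosperms (<0.09), intermediate
#' and declining for other conifers (0.17-0.26), high and rising for *Pinus*
#' (0.17-0.56). Deaths are accounted over the drought window 2014-2016 as
#' seen from a 2016 survey.
#'
#' @param n_plots Number of plots.
#' @param trees_per_plot_mean Mean standing trees (>=5 m tall) per plot;
#'   realized counts are Poisson.
#' @param group_names Taxonomic group labels, in the order used by
#'   `composition_by_height` columns and `mortality_by_cell` rows.
#' @param species_per_group Named list mapping each group to its species.
#' @param height_class_probs Marginal probabilities of the three height
#'   classes (5-15 m, 15-30 m, >30 m) among standing trees.
#' @param composition_by_height 3 x n_groups matrix; row i is the probability
#'   vector over groups for trees of height class i (rows sum to 1). This is
#'   the composition of the population alive at the start of the window.
#' @param mortality_by_cell n_groups x 3 matrix of window mortality
#'   probabilities, rows = groups, columns = height classes.
#' @param dbh_distribution Named list per species: `meanlog`, `sdlog` of a
#'   log-normal DBH distribution (right-skewed, truncated within each height
#'   class's DBH range when sampling).
#' @param retention_model List with `cutpoints` (increasing, years of time
#'   since death) and `scale` (logistic noise scale in years; `0` gives a
#'   deterministic step function). Classes are `R1` (freshest) upward;
#'   number of classes = `length(cutpoints) + 1`.
#' @param survey_year Calendar year of the field survey.
#' @param drought_window Two calendar years, first and last of the mortality
#'   accounting window.
#' @param background_dead_fraction Expected fraction of standing dead trees
#'   whose death pre-dates the window.
#' @param background_death_span Years before the window over which pre-window
#'   deaths are spread uniformly.
#' @param calibration_span Years before the survey covered by death-date
#'   calibration records.
#' @param seed Integer seed; identical configs give byte-identical output.
#' @return A validated object of class `sim_config`.
#' @export
sim_config <- function(n_plots = 89,
                       trees_per_plot_mean = 66,
                       group_names = c("angiosperm", "non_pinus_conifer", "pinus"),
                       species_per_group = default_species_groups(),
                       height_class_probs = c(0.50, 0.35, 0.15),
                       composition_by_height = default_composition(),
                       mortality_by_cell = default_mortality(),
                       dbh_distribution = default_dbh_distribution(),
                       retention_model = list(cutpoints = c(1, 2, 3, 7), scale = 0.3),
                       survey_year = 2016,
                       drought_window = c(2014, 2016),
                       background_dead_fraction = 0.3,
                       background_death_span = 10,
                       calibration_span = 14,
                       seed = 1L) {
  cfg <- structure(
    list(n_plots = n_plots,
         trees_per_plot_mean = trees_per_plot_mean,
         group_names = group_names,
         species_per_group = species_per_group,
         height_class_probs = height_class_probs,
         composition_by_height = composition_by_height,
         mortality_by_cell = mortality_by_cell,
         dbh_distribution = dbh_distribution,
         retention_model = retention_model,
         survey_year = survey_year,
         drought_window = drought_window,
         background_dead_fraction = background_dead_fraction,
         background_death_span = background_death_span,
         calibration_span = calibration_span,
         seed = as.integer(seed)),
    class = "sim_config"
  )
  validate_sim_config(cfg)
}

#' @rdname sim_config
#' @param cfg A `sim_config` to validate.
#' @export
validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  g <- length(cfg$group_names)
  if (!setequal(names(cfg$species_per_group), cfg$group_names)) {
    stop("species_per_group must have exactly one entry per group", call. = FALSE)
  }
  if (length(cfg$height_class_probs) != 3L ||
      abs(sum(cfg$height_class_probs) - 1) > 1e-12) {
    stop("height_class_probs must be 3 probabilities summing to 1", call. = FALSE)
  }
  cm <- cfg$composition_by_height
  if (!is.matrix(cm) || nrow(cm) != 3L || ncol(cm) != g) {
    stop("composition_by_height must be a 3 x ", g, " matrix ",
         "(height classes x groups)", call. = FALSE)
  }
  if (any(abs(rowSums(cm) - 1) > 1e-12) || any(cm < 0)) {
    stop("composition_by_height rows must be probability vectors summing to 1",
         call. = FALSE)
  }
  mm <- cfg$mortality_by_cell
  if (!is.matrix(mm) || nrow(mm) != g || ncol(mm) != 3L) {
    stop("mortality_by_cell must be a ", g, " x 3 matrix (groups x height classes)",
         call. = FALSE)
  }
  if (any(mm < 0 | mm > 1)) {
    stop("mortality probabilities must lie in [0, 1]", call. = FALSE)
  }
  all_sp <- unlist(cfg$species_per_group, use.names = FALSE)
  missing_dbh <- setdiff(all_sp, names(cfg$dbh_distribution))
  if (length(missing_dbh) > 0) {
    stop("dbh_distribution missing species: ", paste(missing_dbh, collapse = ", "),
         call. = FALSE)
  }
  rm <- cfg$retention_model
  if (is.null(rm$cutpoints) || is.unsorted(rm$cutpoints, strictly = TRUE) ||
      is.null(rm$scale) || rm$scale < 0) {
    stop("retention_model needs strictly increasing cutpoints and scale >= 0",
         call. = FALSE)
  }
  if (length(cfg$drought_window) != 2L ||
      cfg$drought_window[1] > cfg$drought_window[2] ||
      cfg$drought_window[2] > cfg$survey_year) {
    stop("drought_window must be [first, last] with last <= survey_year", call. = FALSE)
  }
  if (cfg$background_dead_fraction < 0 || cfg$background_dead_fraction >= 1) {
    stop("background_dead_fraction must be in [0, 1)", call. = FALSE)
  }
  cfg
}

#' @rdname sim_config
#' @export
default_species_groups <- function() {
  list(
    angiosperm = c("Quercus kelloggii", "Quercus chrysolepis", "Cornus nuttallii"),
    non_pinus_conifer = c("Abies concolor", "Abies magnifica",
                          "Calocedrus decurrens", "Torreya californica"),
    pinus = c("Pinus ponderosa", "Pinus lambertiana", "Pinus jeffreyi")
  )
}

#' @rdname sim_config
#' @export
default_composition <- function() {
  m <- rbind(`5-15m`  = c(0.58, 0.36, 0.06),
             `15-30m` = c(0.32, 0.56, 0.12),
             `>30m`   = c(0.10, 0.60, 0.30))
  colnames(m) <- c("angiosperm", "non_pinus_conifer", "pinus")
  m
}

#' @rdname sim_config
#' @export
default_mortality <- function() {
  m <- rbind(angiosperm        = c(0.08, 0.04, 0.015),
             non_pinus_conifer = c(0.26, 0.21, 0.17),
             pinus             = c(0.17, 0.35, 0.56))
  colnames(m) <- c("5-15m", "15-30m", ">30m")
  m
}

#' @rdname sim_config
#' @export
default_dbh_distribution <- function() {
  sp <- default_species_groups()
  mk <- function(meanlog, sdlog) list(meanlog = meanlog, sdlog = sdlog)
  c(
    stats::setNames(rep(list(mk(log(22), 0.60)), length(sp$angiosperm)), sp$angiosperm),
    stats::setNames(rep(list(mk(log(40), 0.70)), length(sp$non_pinus_conifer)),
                    sp$non_pinus_conifer),
    stats::setNames(rep(list(mk(log(45), 0.70)), length(sp$pinus)), sp$pinus)
  )
}

#' Read / write a simulation configuration as YAML
#'
#' The YAML mirrors the `sim_config` field names; matrices are stored as
#' named nested lists (height class -> group probabilities; group -> height
#' class mortalities).
#'
#' @param path File path.
#' @return [read_sim_config()] returns a `sim_config`;
#'   [write_sim_config()] invisibly returns `path`.
#' @export
read_sim_config <- function(path) {
  y <- yaml::read_yaml(path)
  comp <- do.call(rbind, lapply(y$composition_by_height, unlist))
  mort <- do.call(rbind, lapply(y$mortality_by_cell, unlist))
  sim_config(
    n_plots = y$n_plots,
    trees_per_plot_mean = y$trees_per_plot_mean,
    group_names = y$group_names,
    species_per_group = y$species_per_group,
    height_class_probs = unlist(y$height_class_probs),
    composition_by_height = comp,
    mortality_by_cell = mort,
    dbh_distribution = y$dbh_distribution,
    retention_model = y$retention_model,
    survey_year = y$survey_year,
    drought_window = unlist(y$drought_window),
    background_dead_fraction = y$background_dead_fraction,
    background_death_span = y$background_death_span,
    calibration_span = y$calibration_span,
    seed = y$seed
  )
}

#' @rdname read_sim_config
#' @param cfg A `sim_config`.
#' @export
write_sim_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "sim_config"))
  y <- unclass(cfg)
  y$composition_by_height <- apply(cfg$composition_by_height, 1, as.list,
                                   simplify = FALSE)
  y$mortality_by_cell <- apply(cfg$mortality_by_cell, 1, as.list, simplify = FALSE)
  yaml::write_yaml(y, path)
  invisible(path)
}
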