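#' Write the synthetic inputs for a pipeline run
#'
#' Generates the inventory, the death-date calibration set and the truth
#' tables from a [sim_config()] and writes them as headered CSV under
#' `outdir`, together with a small manifest recording the seed and file
#' checksums. Identical configs produce byte-identical files.
#'
#' @param config A [sim_config()].
#' @param outdir Output directory (created if needed).
#' @param allometry Optional allometry list (see [generate_inventory()]).
#' @param n_calibration Calibration records to generate.
#' @return Invisibly, a tibble manifest (file, rows, md5).
#' @export
run_simulate <- function(config, outdir, allometry = NULL, n_calibration = 2297) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  inv <- generate_inventory(config, allometry)
  calib <- generate_calibration(config, n_calibration)
  truth_cells <- inv$truth$cells
  truth_trees <- dplyr::left_join(inv$truth$height_class,
                                  inv$trees[, c("tree_id", "true_death_year")],
                                  by = "tree_id")
  files <- list(
    inventory.csv = inv$trees,
    calibration.csv = calib,
    truth_cells.csv = truth_cells,
    truth_trees.csv = truth_trees
  )
  manifest <- purrr::imap(files, function(df, name) {
    path <- file.path(outdir, name)
    readr::write_csv(df, path, progress = FALSE)
    tibble::tibble(file = name, rows = nrow(df),
                   md5 = unname(tools::md5sum(path)))
  }) |> dplyr::bind_rows()
  manifest_path <- file.path(outdir, "manifest.csv")
  readr::write_csv(dplyr::mutate(manifest, seed = config$seed), manifest_path,
                   progress = FALSE)
  message("simulate: wrote ", nrow(manifest), " tables to ", outdir,
          " (seed ", config$seed, ")")
  invisible(manifest)
}

#' Run the full mortality pipeline
#'
#' Orchestrates every stage on an inventory and calibration set (synthetic by
#' default, or user-supplied tibbles with the same columns):
#' height-class assignment from DBH via the species allometries; gamma
#' death-dating fits and per-snag window probabilities `q`; the per-cell
#' mortality MCMC; back-calculation of start-of-window populations; and the
#' decomposition with both counterfactual standardizations. Trees whose DBH
#' class falls below the species' 5-m threshold are excluded before fitting.
#'
#' @param config A [sim_config()] (supplies the survey calendar and, when
#'   `trees` is `NULL`, the synthetic data).
#' @param trees Optional inventory tibble (columns as in
#'   [generate_inventory()]'s `trees`); default: generate from `config`.
#' @param calibration Optional calibration tibble; default: generate.
#' @param allometry Optional allometry list; default [default_allometry()].
#' @param mcmc An [mcmc_config()]; `smoke = TRUE` overrides it with a short
#'   3 x 2,000 / 500 burn-in run for quick checks.
#' @param gamma_method `"bayes"` or `"mle"` for the death-dating fits.
#' @param map Species -> calibration group map.
#' @param smoke Logical; use reduced MCMC settings.
#' @param outdir Optional directory; when given, all result tables are
#'   written there as CSV.
#' @param rhat_threshold Convergence bound; any cell above it sets
#'   `converged = FALSE` (and the summary flags low effective draw counts).
#' @param focal_group Group whose mortality is flattened in the
#'   constant-group-mortality counterfactual (default `"pinus"`).
#' @return List of tables: `cell_summary` (per group x height class posterior
#'   mean, 95% CI, Rhat, n_eff, n_2016, n_2013, d), `pooled` (per class
#'   pooled M), `composition` (per class p by group), `counterfactual_composition`
#'   (constant-composition M*), `counterfactual_group` (constant focal-group
#'   mortality M*), `reversal` (trend report), `diagnostics`, and `converged`.
#' @export
run_full <- function(config = sim_config(), trees = NULL, calibration = NULL,
                     allometry = NULL, mcmc = mcmc_config(seed = config$seed),
                     gamma_method = "bayes", map = calibration_group_map(),
                     smoke = FALSE, outdir = NULL, rhat_threshold = 1.1,
                     focal_group = "pinus") {
  t0 <- Sys.time()
  if (is.null(allometry)) {
    allometry <- default_allometry(unlist(config$species_per_group,
                                          use.names = FALSE))
  }
  if (is.null(trees)) trees <- generate_inventory(config, allometry)$trees
  if (is.null(calibration)) calibration <- generate_calibration(config)
  if (smoke) {
    mcmc <- mcmc_config(n_chains = 3L, iterations_per_chain = 2000L,
                        burn_in = 500L, seed = mcmc$seed)
  }
  required <- c("tree_id", "species", "group", "dbh_class", "status",
                "retention_class")
  missing_cols <- setdiff(required, names(trees))
  if (length(missing_cols) > 0) {
    stop("inventory is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }

  # 1. height classes from DBH
  sp_list <- unique(trees$species)
  trees$height_class <- NA_character_
  for (sp in sp_list) {
    if (!sp %in% names(allometry)) {
      stop("no allometry for species: ", sp, call. = FALSE)
    }
    th <- compute_thresholds(allometry[[sp]])
    sel <- trees$species == sp
    trees$height_class[sel] <-
      as.character(assign_height_class(trees$dbh_class[sel], th))
  }
  n_below <- sum(trees$height_class == "below-5m")
  trees <- trees[trees$height_class != "below-5m", ]
  message("allometry: assigned height classes (", n_below,
          " trees below 5 m excluded)")

  # 2. death dating
  gm <- fit_gamma_death_model(calibration, map, method = gamma_method,
                              mcmc = mcmc)
  dead <- trees[trees$status == "dead", ]
  qtab <- prob_death_in_window(gm, dead, survey_year = config$survey_year,
                               window = config$drought_window, map = map)
  trees <- dplyr::left_join(trees, qtab, by = "tree_id")
  message("death_dating: fitted ", sum(!is.na(gm$fits$retention_class)),
          " gamma cells (", gamma_method, "); mean q = ",
          round(mean(qtab$q), 3))

  # 3. mortality MCMC
  cells <- tidyr::expand_grid(group = config$group_names,
                              height_class = height_class_levels())
  fit <- fit_mortality(trees, cfg = mcmc, cells = cells)
  summ <- summarize_mortality(fit)
  bc <- back_calculate(summ$n_live, summ$mean)
  cell_summary <- dplyr::bind_cols(
    dplyr::rename(summ, n_2016 = "n_live"), bc)
  gamma_rhat_max <- if (gamma_method == "bayes") {
    max(gm$fits$rhat, na.rm = TRUE)
  } else NA_real_
  converged <- all(cell_summary$rhat < rhat_threshold, na.rm = TRUE) &&
    (is.na(gamma_rhat_max) || gamma_rhat_max < rhat_threshold)
  low_eff <- cell_summary$n_eff < 400
  if (any(low_eff)) {
    warning("low effective draw count (< 400) in ", sum(low_eff), " cell(s)")
  }
  message("mortality_mcmc: ", nrow(cell_summary), " cells, max Rhat = ",
          round(max(cell_summary$rhat, na.rm = TRUE), 4),
          if (converged) " (converged)" else " (NOT converged)")

  # 4. decomposition on back-calculated start-of-window populations
  tab <- decomposition_table(
    tibble::tibble(height_class = cell_summary$height_class,
                   group = cell_summary$group,
                   n = cell_summary$n_2013,
                   d = cell_summary$d))
  pooled <- dplyr::distinct(tab, .data$height_class, .data$M)
  composition <- tab[, c("height_class", "group", "p")]
  ref_p <- tab |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(n = sum(.data$n), .groups = "drop")
  reference_p <- stats::setNames(proportions(ref_p$n), ref_p$group)
  cf_comp <- standardize_composition(tab, reference_p)
  focal <- tab[tab$group == focal_group, ]
  pooled_focal_m <- sum(focal$d) / sum(focal$n)
  cf_group <- standardize_group_mortality(tab, focal_group, pooled_focal_m)
  reversal <- detect_simpson_reversal(tab)
  diagnostics <- cell_summary[, c("group", "height_class", "rhat", "n_eff")]
  message("decomposition: pooled M = ",
          paste(round(pooled$M[match(height_class_levels(),
                                     pooled$height_class)], 3),
                collapse = " / "),
          "; constant-composition M* = ",
          paste(round(cf_comp$M_star[match(height_class_levels(),
                                           cf_comp$height_class)], 3),
                collapse = " / "))

  out <- list(cell_summary = cell_summary, pooled = pooled,
              composition = composition,
              counterfactual_composition = cf_comp,
              counterfactual_group = cf_group,
              reference_p = reference_p,
              reversal = reversal, diagnostics = diagnostics,
              gamma_rhat_max = gamma_rhat_max,
              converged = converged,
              runtime_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(cell_summary, file.path(outdir, "cell_summary.csv"),
                     progress = FALSE)
    readr::write_csv(pooled, file.path(outdir, "pooled_mortality.csv"),
                     progress = FALSE)
    readr::write_csv(composition, file.path(outdir, "composition.csv"),
                     progress = FALSE)
    readr::write_csv(cf_comp,
                     file.path(outdir, "counterfactual_composition.csv"),
                     progress = FALSE)
    readr::write_csv(cf_group, file.path(outdir, "counterfactual_group.csv"),
                     progress = FALSE)
    readr::write_csv(diagnostics, file.path(outdir, "diagnostics.csv"),
                     progress = FALSE)
  }
  out
}
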