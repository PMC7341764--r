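#' Species-specific height-diameter allometry
#'
#' Constructs the parameter set used to translate a tree's diameter at breast
#' height (DBH, cm) into a predicted total height (m). Two functional forms are
#' supported:
#'
#' * `"chapman_richards"`: a saturating curve
#'   \eqn{H(D) = 1.37 + A (1 - e^{-k D})^{c}}, with asymptote `A` (m above
#'   breast height), rate `k` (1/cm) and shape `c` (dimensionless). This is the
#'   workhorse form for conifer and hardwood height-diameter fits.
#' * `"linear"`: \eqn{H(D) = 1.37 + b D}, a toy form convenient for exact
#'   hand-checked inversions.
#'
#' Breast height is fixed at 1.37 m, the field convention used when recording
#' DBH, so every curve passes through 1.37 m at `dbh = 0`.
#'
#' @param species Species label.
#' @param form `"chapman_richards"` or `"linear"`.
#' @param ... Named positive parameters for the form: `A`, `k`, `c` for
#'   `"chapman_richards"`; `b` for `"linear"`.
#' @return An object of class `allometry_params`.
#' @examples
#' ap <- allometry_params("Abies concolor", "chapman_richards",
#'                        A = 58, k = 0.022, c = 1.2)
#' predict_height(ap, 50)
#' @export
allometry_params <- function(species, form = c("chapman_richards", "linear"), ...) {
  form <- match.arg(form)
  pars <- list(...)
  needed <- switch(form, chapman_richards = c("A", "k", "c"), linear = "b")
  missing <- setdiff(needed, names(pars))
  if (length(missing) > 0) {
    stop("allometry form '", form, "' requires parameter(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  vals <- unlist(pars[needed])
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("allometry parameters must be finite and strictly positive", call. = FALSE)
  }
  structure(
    list(species = species, form = form, parameters = pars[needed],
         breast_height = 1.37),
    class = "allometry_params"
  )
}

#' Predict tree height from DBH
#'
#' Evaluates the species' height-diameter curve. Strictly increasing in DBH
#' and tends to `breast_height` as DBH tends to zero; a saturating form tends
#' to `A + 1.37` m as DBH grows without bound.
#'
#' @param params An [allometry_params()] object.
#' @param dbh DBH in cm; vectorized, all values must be > 0.
#' @return Predicted height(s) in m.
#' @export
predict_height <- function(params, dbh) {
  stopifnot(inherits(params, "allometry_params"))
  if (any(!is.finite(dbh)) || any(dbh <= 0)) {
    stop("dbh must be finite and > 0", call. = FALSE)
  }
  p <- params$parameters
  bh <- params$breast_height
  switch(params$form,
    chapman_richards = bh + p$A * (1 - exp(-p$k * dbh))^p$c,
    linear = bh + p$b * dbh
  )
}

#' DBH thresholds between height classes
#'
#' Inverts the height-diameter curve at each height break (default 5, 15 and
#' 30 m, the boundaries of the 5-15 m, 15-30 m and >30 m classes) and rounds
#' the resulting DBH to the nearest 5-cm class boundary, because inventory DBH
#' is recorded in 5-cm classes. An exact tie (x.5 on the 5-cm scale, i.e.
#' 2.5 cm from both neighbours) rounds up. A break above the curve's attainable
#' height yields `NA` ("unreachable") for that threshold.
#'
#' Inversion is numerical bisection to 0.01 cm, so any monotone form is
#' supported without a closed-form inverse.
#'
#' @param params An [allometry_params()] object.
#' @param height_breaks Increasing heights (m) at which to place thresholds.
#' @param bin_width DBH class width in cm (default 5).
#' @return A `height_class_thresholds` object: species plus a named numeric
#'   vector `dbh_at` of rounded thresholds (cm), `NA` where unreachable.
#' @export
compute_thresholds <- function(params, height_breaks = c(5, 15, 30), bin_width = 5) {
  stopifnot(inherits(params, "allometry_params"))
  if (is.unsorted(height_breaks, strictly = TRUE)) {
    stop("height_breaks must be strictly increasing", call. = FALSE)
  }
  # sanity: monotone over a coarse grid
  grid <- seq(0.5, 500, by = 0.5)
  hg <- predict_height(params, grid)
  if (any(diff(hg) <= 0)) stop("height curve is not strictly increasing", call. = FALSE)

  invert_one <- function(target) {
    lo <- 1e-6
    hi <- 10
    while (predict_height(params, hi) < target && hi < 1e6) hi <- hi * 2
    if (predict_height(params, hi) < target) return(NA_real_)  # unreachable
    while (hi - lo > 0.01) {
      mid <- (lo + hi) / 2
      if (predict_height(params, mid) < target) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }
  exact <- vapply(height_breaks, invert_one, numeric(1))
  # nearest 5-cm class; ties (exactly halfway) round up
  rounded <- ifelse(is.na(exact), NA_real_,
                    floor(exact / bin_width + 0.5) * bin_width)
  structure(
    list(species = params$species,
         height_breaks = height_breaks,
         dbh_at = stats::setNames(rounded, paste0("dbh_at_", height_breaks, "m"))),
    class = "height_class_thresholds"
  )
}

#' Height-class labels used throughout the pipeline
#'
#' @return Character vector `c("5-15m", "15-30m", ">30m")`.
#' @export
height_class_levels <- function() c("5-15m", "15-30m", ">30m")

#' Assign trees to height classes from their DBH class
#'
#' Compares the 5-cm DBH class label (the bin's lower edge, cm) against the
#' species' thresholds. The convention, documented and tested, is that a DBH
#' class equal to a threshold belongs to the taller class (`>=`). Trees whose
#' DBH class falls below the 5-m threshold are labelled `"below-5m"`; the
#' mortality analysis covers trees at least 5 m tall, so these are excluded
#' upstream of model fitting.
#'
#' @param dbh_class Numeric vector of 5-cm bin lower edges (cm).
#' @param thresholds A `height_class_thresholds` object for the trees' species
#'   with breaks 5, 15 and 30 m.
#' @return Factor with levels `"below-5m"`, `"5-15m"`, `"15-30m"`, `">30m"`.
#' @export
assign_height_class <- function(dbh_class, thresholds) {
  stopifnot(inherits(thresholds, "height_class_thresholds"))
  th <- thresholds$dbh_at
  if (!all(c("dbh_at_5m", "dbh_at_15m", "dbh_at_30m") %in% names(th))) {
    stop("thresholds must carry breaks at 5, 15 and 30 m", call. = FALSE)
  }
  cuts <- c(th[["dbh_at_5m"]], th[["dbh_at_15m"]], th[["dbh_at_30m"]])
  labs <- c("below-5m", height_class_levels())
  # NA threshold = class unreachable for this species; treat as +Inf cut
  cuts[is.na(cuts)] <- Inf
  idx <- 1L + rowSums(outer(dbh_class, cuts, `>=`))
  factor(labs[idx], levels = labs)
}

#' Default allometry table for the synthetic landscape
#'
#' One saturating curve per species, parameterized so that mature angiosperms
#' top out near 35-40 m while the large conifers can exceed 55 m, broadly
#' matching Sierra Nevada mixed-conifer stature. These are stand-ins for
#' published species-specific equations and are fully configurable.
#'
#' @param species Optional character vector restricting the table.
#' @return Named list of [allometry_params()] keyed by species.
#' @export
default_allometry <- function(species = NULL) {
  tab <- list(
    "Quercus kelloggii"    = c(A = 34, k = 0.030, c = 1.15),
    "Quercus chrysolepis"  = c(A = 33, k = 0.028, c = 1.15),
    "Cornus nuttallii"     = c(A = 32, k = 0.034, c = 1.10),
    "Abies concolor"       = c(A = 58, k = 0.020, c = 1.25),
    "Abies magnifica"      = c(A = 60, k = 0.019, c = 1.25),
    "Calocedrus decurrens" = c(A = 52, k = 0.021, c = 1.30),
    "Torreya californica"  = c(A = 36, k = 0.026, c = 1.20),
    "Pinus ponderosa"      = c(A = 62, k = 0.019, c = 1.20),
    "Pinus lambertiana"    = c(A = 64, k = 0.018, c = 1.20),
    "Pinus jeffreyi"       = c(A = 60, k = 0.019, c = 1.20)
  )
  if (!is.null(species)) {
    unknown <- setdiff(species, names(tab))
    if (length(unknown) > 0) {
      stop("no default allometry for species: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    tab <- tab[species]
  }
  lapply(names(tab), function(sp) {
    p <- tab[[sp]]
    allometry_params(sp, "chapman_richards", A = p[["A"]], k = p[["k"]], c = p[["c"]])
  }) |> stats::setNames(names(tab))
}

#' Read an allometry parameter table from CSV
#'
#' Expected columns: `species`, `form`, then one column per named parameter
#' (`A`, `k`, `c` for the saturating form; `b` for the linear form); unused
#' parameter columns may be left blank.
#'
#' @param path CSV path.
#' @return Named list of [allometry_params()].
#' @export
read_allometry <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  stopifnot(all(c("species", "form") %in% names(df)))
  out <- lapply(seq_len(nrow(df)), function(i) {
    row <- df[i, ]
    pars <- as.list(row[setdiff(names(row), c("species", "form"))])
    pars <- pars[!vapply(pars, function(x) is.na(x), logical(1))]
    do.call(allometry_params, c(list(species = row$species, form = row$form), pars))
  })
  stats::setNames(out, df$species)
}

# Thresholds for a list of allometries, as a tibble keyed by species.
threshold_table <- function(allom, height_breaks = c(5, 15, 30)) {
  rows <- lapply(allom, function(ap) {
    th <- compute_thresholds(ap, height_breaks)
    tibble::tibble(species = ap$species,
                   dbh_at_5m = th$dbh_at[[1]],
                   dbh_at_15m = th$dbh_at[[2]],
                   dbh_at_30m = th$dbh_at[[3]])
  })
  dplyr::bind_rows(rows)
}
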