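#' Pooled mortality of a height class
#'
#' The overall fractional mortality of height class i pools deaths over
#' the start-of-window populations of its x >= 2 taxonomic groups:
#' \deqn{M_i = (d_{i,1} + \dots + d_{i,x}) / (n_{i,1} + \dots + n_{i,x}),}
#' which is algebraically the composition-weighted mean of the group
#' mortalities, \eqn{M_i = \sum_t m_{i,t} p_{i,t}} with
#' \eqn{p_{i,t} = n_{i,t} / \sum_t n_{i,t}}. Inputs are real-valued (they are
#' typically posterior means and back-calculated populations).
#'
#' @param n Per-group start-of-window populations (all >= 0, sum > 0).
#' @param d Per-group deaths, `0 <= d <= n`.
#' @return Pooled fractional mortality `M`.
#' @export
pooled_mortality <- function(n, d) {
  if (length(n) != length(d)) stop("n and d lengths differ", call. = FALSE)
  if (any(n < 0) || any(d < 0) || any(d > n + 1e-9)) {
    stop("need 0 <= d <= n in every group", call. = FALSE)
  }
  if (sum(n) <= 0) stop("pooled mortality undefined: no trees", call. = FALSE)
  sum(d) / sum(n)
}

#' Group proportions within a height class
#'
#' `p_t = n_t / sum(n)`, the relative abundances of the taxonomic groups
#' among trees alive at the start of the window.
#'
#' @param n Per-group populations (non-negative, sum > 0).
#' @return Proportion vector summing to 1 (names preserved).
#' @export
proportions <- function(n) {
  if (any(n < 0)) stop("negative counts", call. = FALSE)
  if (sum(n) <= 0) stop("proportions undefined: no trees", call. = FALSE)
  n / sum(n)
}

#' Assemble a decomposition table
#'
#' One row per (height class, group) with populations `n`, deaths `d`,
#' group mortality `m = d/n`, within-class proportions `p`, and the pooled
#' class mortality `M` attached to every row of the class.
#'
#' @param df Tibble with columns `height_class`, `group`, `n`, `d`.
#' @return Tibble with added `m`, `p`, `M`, ordered by height class.
#' @export
decomposition_table <- function(df) {
  stopifnot(all(c("height_class", "group", "n", "d") %in% names(df)))
  df |>
    dplyr::group_by(.data$height_class) |>
    dplyr::mutate(m = ifelse(.data$n > 0, .data$d / .data$n, 0),
                  p = proportions(.data$n),
                  M = pooled_mortality(.data$n, .data$d)) |>
    dplyr::ungroup()
}

#' Counterfactual: constant composition across height classes
#'
#' Direct standardization. Recomputes each class's pooled mortality from its
#' actual group mortalities but a fixed reference composition (typically the
#' composition of the whole start-of-window population):
#' \eqn{M_i^* = \sum_t m_{i,t}\, p^{ref}_t}. If the height trend of the
#' observed pooled M disappears (or reverses) under standardization, that
#' trend was carried by height-related composition change, not by the
#' within-group mortalities.
#'
#' @param tab A [decomposition_table()] output.
#' @param reference_p Named proportion vector over groups (sums to 1); names
#'   must match the table's groups.
#' @return Tibble: `height_class`, `M_star`.
#' @export
standardize_composition <- function(tab, reference_p) {
  groups <- unique(tab$group)
  if (is.null(names(reference_p)) || !setequal(names(reference_p), groups)) {
    stop("reference_p must be named with exactly the table's groups", call. = FALSE)
  }
  if (abs(sum(reference_p) - 1) > 1e-9) {
    stop("reference_p must sum to 1", call. = FALSE)
  }
  tab |>
    dplyr::group_by(.data$height_class) |>
    dplyr::summarise(
      M_star = sum(.data$m * reference_p[.data$group]),
      .groups = "drop"
    ) |>
    dplyr::arrange(match(.data$height_class, unique(tab$height_class)))
}

#' Counterfactual: constant mortality for one group
#'
#' Recomputes each class's pooled mortality with the actual compositions and
#' the actual mortalities of every other group, but with the focal group's
#' mortality replaced by a single pooled value in every class (typically the
#' group's whole-population mortality). Isolates how much of the height trend
#' is contributed by that group's own height-mortality gradient.
#'
#' @param tab A [decomposition_table()] output.
#' @param group Focal group label.
#' @param pooled_m Replacement mortality in `[0, 1]`.
#' @return Tibble: `height_class`, `M_star`.
#' @export
standardize_group_mortality <- function(tab, group, pooled_m) {
  if (!group %in% tab$group) stop("unknown group: ", group, call. = FALSE)
  if (pooled_m < 0 || pooled_m > 1) stop("pooled_m must be in [0, 1]", call. = FALSE)
  focal <- group
  tab |>
    dplyr::mutate(m_cf = ifelse(.data$group == focal, pooled_m, .data$m)) |>
    dplyr::group_by(.data$height_class) |>
    dplyr::summarise(M_star = sum(.data$m_cf * .data$p), .groups = "drop") |>
    dplyr::arrange(match(.data$height_class, unique(tab$height_class)))
}

# Classify a sequence as increasing / decreasing / constant / non-monotone
# under strict comparisons with a tolerance for float ties.
trend_direction <- function(x, tol = 1e-9) {
  dx <- diff(x)
  if (all(abs(dx) <= tol)) return("constant")
  if (all(dx > tol)) return("increasing")
  if (all(dx < -tol)) return("decreasing")
  "non-monotone"
}

#' Detect a Simpson-type reversal between pooled and group mortality trends
#'
#' Classifies the height trend of each group's mortality and of the pooled
#' mortality (strictly increasing / decreasing / constant / non-monotone,
#' with a float-tie tolerance). A reversal is flagged when the pooled trend
#' is strictly monotone while the groups holding at least `majority` of the
#' trees trend strictly in the opposite direction — the pattern in which a
#' height-related composition shift, not within-group vulnerability, drives
#' the pooled trend. When groups trend in opposite directions (and no
#' composition-driven reversal holds), the pattern is reported as
#' `opposing_trends` instead.
#'
#' @param tab A [decomposition_table()] output with >= 2 height classes.
#' @param majority Minimum fraction of trees (start-of-window populations)
#'   that must sit in groups opposing the pooled trend (default 0.75).
#' @param tol Strictness tolerance for trend comparisons.
#' @param class_order Height classes from shortest to tallest; defaults to
#'   [height_class_levels()] when the table uses those labels, otherwise to
#'   first appearance order.
#' @return List: `group_trends` (tibble `group`, `trend`, `tree_share`),
#'   `pooled_trend`, `opposing_share` (tree share in groups trending against
#'   the pooled direction), `reversal` (logical), `opposing_trends` (logical:
#'   some groups increase while others decrease).
#' @export
detect_simpson_reversal <- function(tab, majority = 0.75, tol = 1e-9,
                                    class_order = NULL) {
  classes <- unique(tab$height_class)
  if (is.null(class_order)) {
    class_order <- if (all(classes %in% height_class_levels())) {
      intersect(height_class_levels(), classes)
    } else classes
  }
  if (!setequal(class_order, classes)) {
    stop("class_order must contain exactly the table's height classes",
         call. = FALSE)
  }
  classes <- class_order
  if (length(classes) < 2L) stop("need at least 2 height classes", call. = FALSE)
  wide_m <- tab |>
    dplyr::arrange(match(.data$height_class, classes)) |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(trend = trend_direction(.data$m, tol),
                     n_total = sum(.data$n), .groups = "drop") |>
    dplyr::mutate(tree_share = .data$n_total / sum(.data$n_total))
  pooled <- tab |>
    dplyr::distinct(.data$height_class, .data$M) |>
    dplyr::arrange(match(.data$height_class, classes))
  pooled_trend <- trend_direction(pooled$M, tol)
  opposite <- switch(pooled_trend, increasing = "decreasing",
                     decreasing = "increasing", NA_character_)
  opposing_share <- if (is.na(opposite)) 0 else
    sum(wide_m$tree_share[wide_m$trend == opposite])
  reversal <- !is.na(opposite) && opposing_share >= majority
  opposing_trends <- all(c("increasing", "decreasing") %in% wide_m$trend)
  list(group_trends = wide_m[, c("group", "trend", "tree_share")],
       pooled_trend = pooled_trend,
       opposing_share = opposing_share,
       reversal = reversal,
       opposing_trends = opposing_trends)
}
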