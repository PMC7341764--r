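#' Hypothetical two-group scenario tables
#'
#' Builds a [decomposition_table()] for a stylized drought-stricken forest of
#' two taxonomic groups, given each class's group proportions, group
#' mortalities and a class population size. These are the teaching scenarios
#' that motivate the decomposition: a pooled mortality trend can contradict
#' every group's own trend once composition shifts with height.
#'
#' @param p_b Proportion of group B per height class (vector, one entry per
#'   class); group A gets the complement.
#' @param m_a,m_b Group mortalities per height class, in `[0, 1]`.
#' @param n_total Trees per height class (scalar or vector).
#' @param height_classes Class labels.
#' @param groups Two group labels, `c(A, B)`.
#' @return A decomposition table (real-valued counts).
#' @export
scenario_table <- function(p_b, m_a, m_b, n_total = 1000,
                           height_classes = NULL,
                           groups = c("A", "B")) {
  k <- length(p_b)
  if (length(m_a) != k || length(m_b) != k) {
    stop("p_b, m_a, m_b must have one entry per height class", call. = FALSE)
  }
  if (any(p_b < 0 | p_b > 1)) stop("proportions must lie in [0, 1]", call. = FALSE)
  if (any(c(m_a, m_b) < 0 | c(m_a, m_b) > 1)) {
    stop("mortalities must lie in [0, 1]", call. = FALSE)
  }
  if (length(groups) != 2L) stop("scenarios have exactly two groups", call. = FALSE)
  if (is.null(height_classes)) height_classes <- paste0("class", seq_len(k))
  n_total <- rep_len(n_total, k)
  df <- tibble::tibble(
    height_class = rep(height_classes, each = 2L),
    group = rep(groups, times = k),
    n = as.numeric(rbind((1 - p_b) * n_total, p_b * n_total))
  )
  m <- as.numeric(rbind(m_a, m_b))
  df$d <- df$n * m
  decomposition_table(df)
}

#' Bundled scenario presets
#'
#' `scenario_preset("shared-decline")` (scenario 1): both groups' mortality
#' declines with height, group B is uniformly more vulnerable than group A,
#' and B's relative abundance rises steeply with height — so pooled mortality
#' *rises* with height although every group's mortality falls: a Simpson
#' reversal driven purely by composition.
#'
#' `scenario_preset("opposing-trends")` (scenario 2): group C's mortality
#' declines gently while minority group D's rises sharply, with composition
#' held constant across classes — pooled mortality rises with height without
#' any composition shift.
#'
#' @param name `"shared-decline"` or `"opposing-trends"`.
#' @return A decomposition table (see [scenario_table()]).
#' @export
scenario_preset <- function(name = c("shared-decline", "opposing-trends")) {
  name <- match.arg(name)
  classes <- height_class_levels()
  switch(name,
    "shared-decline" = scenario_table(
      p_b = c(0.1, 0.5, 0.9),
      m_a = c(0.30, 0.20, 0.10),
      m_b = c(0.60, 0.50, 0.40),
      height_classes = classes,
      groups = c("A", "B")
    ),
    "opposing-trends" = scenario_table(
      p_b = c(0.3, 0.3, 0.3),
      m_a = c(0.30, 0.25, 0.20),
      m_b = c(0.10, 0.35, 0.70),
      height_classes = classes,
      groups = c("C", "D")
    )
  )
}
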