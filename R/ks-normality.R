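#' Two-sample Kolmogorov-Smirnov distribution comparison
#'
#' Computes the two-sample KS statistic D — the largest absolute gap
#' between the two empirical distribution functions — from its definition,
#' and a p-value via [stats::ks.test()] (exact enumeration when both
#' samples have at most 10 values and no ties, asymptotic otherwise). D is
#' the primary quantity: it is 0 iff the empirical distributions coincide
#' and 1 iff the samples are fully separated.
#'
#' @param x Numeric vector (sample A), or a data frame (then supply
#'   `value` and `group` as for [perm_mean_test()]).
#' @param y Numeric vector (sample B).
#' @param value,group Data-frame method columns.
#' @param ... Passed between methods.
#' @return A one-row tibble: `d_statistic`, `p_value`, `n1`, `n2`,
#'   `p_method` (`"exact"` or `"asymptotic"`).
#' @examples
#' ks_compare(c(1, 3), c(2, 4)) # D = 0.5
#' @export
ks_compare <- function(x, ...) UseMethod("ks_compare")

#' @rdname ks_compare
#' @export
ks_compare.default <- function(x, y, ...) {
  a <- as.numeric(x)
  b <- as.numeric(y)
  if (length(a) == 0L || length(b) == 0L) abort("both samples must be nonempty.")
  if (anyNA(a) || anyNA(b)) abort("samples must be non-missing.")

  # D from the ECDF definition, evaluated at the pooled support
  xs <- sort(unique(c(a, b)))
  ecdf_a <- vapply(xs, function(v) mean(a <= v), numeric(1))
  ecdf_b <- vapply(xs, function(v) mean(b <= v), numeric(1))
  d <- max(abs(ecdf_a - ecdf_b))

  exact <- length(a) <= 10L && length(b) <= 10L && !anyDuplicated(c(a, b))
  p <- suppressWarnings(ks.test(a, b, exact = exact)$p.value)
  tibble(
    d_statistic = d,
    p_value = p,
    n1 = length(a),
    n2 = length(b),
    p_method = if (exact) "exact" else "asymptotic"
  )
}

#' @rdname ks_compare
#' @export
ks_compare.data.frame <- function(x, value, group, ...) {
  v <- eval_tidy(enquo(value), x)
  g <- eval_tidy(enquo(group), x)
  lev <- unique(g)
  if (length(lev) != 2L) abort("`group` must have exactly two levels.")
  ks_compare(v[g == lev[1]], v[g == lev[2]])
}

#' Normality gate: choose the parametric or nonparametric branch
#'
#' The branch-selection rule used before two-group comparisons: each group
#' is Shapiro-Wilk tested, and the parametric branch is taken only when
#' every group looks normal (all Shapiro p-values strictly above `alpha`);
#' otherwise the nonparametric branch is taken.
#'
#' @param shapiro_p Numeric vector of per-group Shapiro-Wilk p-values.
#' @param alpha Gate level (default 0.05).
#' @return `"parametric"` or `"nonparametric"`.
#' @seealso [shapiro_gate()] to compute the p-values from raw data.
#' @examples
#' normality_gate(c(0.2, 0.6))  # parametric
#' normality_gate(c(0.2, 0.01)) # nonparametric
#' @export
normality_gate <- function(shapiro_p, alpha = 0.05) {
  if (length(shapiro_p) == 0L) abort("need at least one group p-value.")
  if (!is.numeric(shapiro_p) || anyNA(shapiro_p) ||
      any(shapiro_p < 0 | shapiro_p > 1)) {
    abort("Shapiro p-values must lie in [0, 1].")
  }
  .check_number(alpha, "alpha", lower = 0, upper = 1)
  if (all(shapiro_p > alpha)) "parametric" else "nonparametric"
}

#' Shapiro-Wilk test per group, then the normality gate
#'
#' @param data A data frame.
#' @param value,group Bare column names of the statistic and group label.
#' @param alpha Gate level (default 0.05).
#' @return A list: `per_group` (tibble of group, n, shapiro_p) and
#'   `branch` from [normality_gate()].
#' @export
shapiro_gate <- function(data, value, group, alpha = 0.05) {
  v <- eval_tidy(enquo(value), data)
  g <- eval_tidy(enquo(group), data)
  tab <- tibble(group = g, value = v) |>
    group_by(.data$group) |>
    summarise(
      n = dplyr::n(),
      shapiro_p = shapiro.test(.data$value)$p.value,
      .groups = "drop"
    )
  list(per_group = tab, branch = normality_gate(tab$shapiro_p, alpha))
}
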