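#' Surrogate-based permutation test for a two-group mean difference
#'
#' Tests whether two groups of per-neuron statistic values (e.g. firing
#' rate or %SWB) differ in mean, using label-permutation surrogates rather
#' than a parametric model. The observed statistic is the absolute
#' difference of group means. The two groups are pooled and values are
#' repeatedly reassigned at random, without replacement, to groups of the
#' original sizes; for each surrogate the absolute mean difference is
#' recomputed, and the test counts surrogates whose difference is at least
#' as large as the observed one (ties count as exceedances). The p
#' estimate is exceedance count / number of surrogates, with no +1
#' correction; when the count is 0 a note reminds that the true p is then
#' only bounded above by 1/N. Significance stars follow
#' [significance_stars()].
#'
#' With `exhaustive = TRUE` and at most `exhaustive_cap` distinct
#' assignments (group labels are exchangeable within a group, so
#' assignments are combinations), all assignments are enumerated instead
#' of sampled and the p estimate is exact.
#'
#' @param x Numeric vector (group A), or a data frame (see the data-frame
#'   method).
#' @param y Numeric vector (group B) when `x` is a vector.
#' @param n_surrogates Number of random surrogates (default 10000).
#' @param seed Integer seed for the surrogate draws (required for the
#'   Monte-Carlo path).
#' @param exhaustive Enumerate all assignments when feasible.
#' @param exhaustive_cap Maximum number of distinct assignments that will
#'   be enumerated (default 10000).
#' @param value,group For the data-frame method: bare column names of the
#'   statistic and the group label (exactly two levels).
#' @param ... Passed between methods.
#' @return An object of class `da_perm_test`: a list with
#'   `observed_delta`, `exceedance_count`, `n_surrogates`, `p_estimate`,
#'   `stars`, `seed`, `method` (`"monte-carlo"` or `"exhaustive"`), group
#'   sizes, and the vector of surrogate deltas. Has `print()`, `tidy()`,
#'   `glance()` and `autoplot()` methods.
#' @examples
#' res <- perm_mean_test(c(10, 12, 30), c(8, 9, 11), n_surrogates = 1000,
#'                       seed = 1)
#' tidy(res)
#' perm_mean_test(c(0, 0), c(10, 10), exhaustive = TRUE)
#' @export
perm_mean_test <- function(x, ...) UseMethod("perm_mean_test")

#' @rdname perm_mean_test
#' @export
perm_mean_test.default <- function(x, y, n_surrogates = 10000, seed = NULL,
                                   exhaustive = FALSE,
                                   exhaustive_cap = 10000, ...) {
  a <- as.numeric(x)
  b <- as.numeric(y)
  if (length(a) < 2L || length(b) < 2L) {
    abort("each group needs at least 2 values.")
  }
  if (anyNA(a) || anyNA(b) || any(!is.finite(c(a, b)))) {
    abort("group values must be finite and non-missing.")
  }
  .check_number(n_surrogates, "n_surrogates", lower = 1)

  pool <- c(a, b)
  n1 <- length(a)
  n <- length(pool)
  tot <- sum(pool)
  observed <- abs(mean(a) - mean(b))

  delta_from_sumA <- function(sA) abs(sA / n1 - (tot - sA) / (n - n1))

  n_assign <- choose(n, n1)
  if (isTRUE(exhaustive) && n_assign <= exhaustive_cap) {
    idx <- combn(n, n1)
    deltas <- delta_from_sumA(colSums(matrix(pool[idx], nrow = n1)))
    method <- "exhaustive"
    n_surr <- length(deltas)
    used_seed <- NA_integer_
  } else {
    if (isTRUE(exhaustive)) {
      inform(sprintf(
        "%.0f distinct assignments exceed exhaustive_cap = %d; using Monte-Carlo surrogates.",
        n_assign, exhaustive_cap
      ))
    }
    used_seed <- .check_seed(seed)
    n_surr <- as.integer(n_surrogates)
    deltas <- withr::with_seed(used_seed, {
      vapply(seq_len(n_surr), function(i) {
        delta_from_sumA(sum(pool[sample.int(n, n1)]))
      }, numeric(1))
    })
    method <- "monte-carlo"
  }

  count <- sum(deltas >= observed) # ties are exceedances, per the ">=" rule
  p <- count / n_surr
  if (count == 0L) {
    inform(sprintf(
      "no surrogate reached the observed difference; p is reported as 0 but is only bounded above by 1/%d.",
      n_surr
    ))
  }
  structure(
    list(
      observed_delta = observed,
      exceedance_count = count,
      n_surrogates = n_surr,
      p_estimate = p,
      stars = significance_stars(count, n_surr),
      seed = used_seed,
      method = method,
      n1 = n1,
      n2 = n - n1,
      surrogate_deltas = deltas
    ),
    class = "da_perm_test"
  )
}

#' @rdname perm_mean_test
#' @export
perm_mean_test.data.frame <- function(x, value, group, ...) {
  v <- eval_tidy(enquo(value), x)
  g <- eval_tidy(enquo(group), x)
  lev <- unique(g)
  if (length(lev) != 2L) abort("`group` must have exactly two levels.")
  out <- perm_mean_test(v[g == lev[1]], v[g == lev[2]], ...)
  out$groups <- as.character(lev)
  out
}

#' Exceedance-count significance rule
#'
#' Converts a surrogate exceedance count into a star level. At N = 10000
#' surrogates, significance is declared at P < 0.05 / 0.01 / 0.001 exactly
#' when the count is strictly below 500 / 100 / 10; for other N the
#' thresholds scale proportionally (fractions 0.05, 0.01, 0.001). The
#' strictest attained level is returned, else `"ns"`.
#'
#' @param count Number of surrogates with a difference at least as large
#'   as the observed one.
#' @param n Number of surrogates.
#' @return One of `"***"`, `"**"`, `"*"`, `"ns"`.
#' @examples
#' significance_stars(499, 10000) # "*"
#' significance_stars(500, 10000) # "ns"
#' significance_stars(9, 10000)   # "***"
#' @export
significance_stars <- function(count, n) {
  .check_number(n, "n", lower = 1)
  .check_number(count, "count", lower = 0, upper = n)
  if (count < 0.001 * n) return("***")
  if (count < 0.01 * n) return("**")
  if (count < 0.05 * n) return("*")
  "ns"
}

#' @export
print.da_perm_test <- function(x, ...) {
  cat("Surrogate permutation test of mean difference (", x$method, ")\n",
      sep = "")
  cat(sprintf("  groups: n1 = %d, n2 = %d\n", x$n1, x$n2))
  cat(sprintf("  observed |mean difference| = %.4g\n", x$observed_delta))
  cat(sprintf("  exceedances: %d / %d surrogates (p = %.4g) %s\n",
              x$exceedance_count, x$n_surrogates, x$p_estimate, x$stars))
  invisible(x)
}

#' @method tidy da_perm_test
#' @export
tidy.da_perm_test <- function(x, ...) {
  tibble(
    estimate = x$observed_delta,
    exceedance_count = x$exceedance_count,
    p.value = x$p_estimate,
    stars = x$stars,
    method = x$method
  )
}

#' @method glance da_perm_test
#' @export
glance.da_perm_test <- function(x, ...) {
  tibble(
    n_surrogates = x$n_surrogates,
    n1 = x$n1,
    n2 = x$n2,
    seed = x$seed,
    method = x$method
  )
}
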