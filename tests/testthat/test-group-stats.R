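test_that("star rule reproduces the 500/100/10 thresholds and scales with N", {
  expect_equal(significance_stars(499, 10000), "*")
  expect_equal(significance_stars(500, 10000), "ns")
  expect_equal(significance_stars(99, 10000), "**")
  expect_equal(significance_stars(100, 10000), "*")
  expect_equal(significance_stars(9, 10000), "***")
  expect_equal(significance_stars(10, 10000), "**")
  # proportional scaling at other N
  expect_equal(significance_stars(49, 1000), "*")
  expect_equal(significance_stars(50, 1000), "ns")
  expect_equal(significance_stars(0, 1000), "***")
  expect_error(significance_stars(11, 10), "count")
})

test_that("exhaustive enumeration gives the exact permutation p", {
  res <- perm_mean_test(c(0, 0), c(10, 10), exhaustive = TRUE)
  expect_equal(res$p_estimate, 1 / 3)
  expect_equal(res$method, "exhaustive")
  expect_equal(res$n_surrogates, 6L)
  expect_equal(res$exceedance_count, 2L)
})

test_that("identical groups give delta 0, full exceedance, ns", {
  x <- c(1, 2, 3, 4)
  res <- perm_mean_test(x, x, n_surrogates = 500, seed = 1)
  expect_equal(res$observed_delta, 0)
  expect_equal(res$exceedance_count, 500L) # every surrogate delta >= 0
  expect_equal(res$p_estimate, 1)
  expect_equal(res$stars, "ns")
})

test_that("permutation test is deterministic, symmetric and on the p grid", {
  a <- c(5, 9, 13, 30)
  b <- c(2, 4, 6, 7, 8)
  r1 <- perm_mean_test(a, b, n_surrogates = 2000, seed = 77)
  r2 <- perm_mean_test(a, b, n_surrogates = 2000, seed = 77)
  expect_identical(r1$surrogate_deltas, r2$surrogate_deltas)
  expect_identical(r1$p_estimate, r2$p_estimate)
  # p lives on {0, 1/N, ..., 1}
  expect_equal(r1$p_estimate * 2000, round(r1$p_estimate * 2000))
  # swapping the groups leaves the observed delta exactly unchanged and
  # the exact p unchanged
  r3 <- perm_mean_test(b, a, n_surrogates = 2000, seed = 77)
  expect_equal(r3$observed_delta, r1$observed_delta)
  e1 <- perm_mean_test(a, b, exhaustive = TRUE)
  e2 <- perm_mean_test(b, a, exhaustive = TRUE)
  expect_equal(e1$p_estimate, e2$p_estimate)

  expect_error(perm_mean_test(1, b, seed = 1), "at least 2")
  expect_error(perm_mean_test(c(1, NA), b, seed = 1), "finite")
  # a zero exceedance count is reported but flagged as bounded, not zero
  expect_message(
    perm_mean_test(c(1, 1, 1), c(100, 100, 100), n_surrogates = 10, seed = 1),
    "bounded"
  )
})

test_that("Monte-Carlo p converges to the exhaustive p", {
  # small-n oracle check; the 50-dataset version runs in the acceptance suite
  withr::with_seed(15, {
    for (rep in 1:8) {
      a <- rlnorm(4, 3, 0.6)
      b <- rlnorm(4, 3, 0.6) + rnorm(1, 0, 5)
      exact <- perm_mean_test(a, b, exhaustive = TRUE)$p_estimate
      mc <- perm_mean_test(a, b, n_surrogates = 10000,
                           seed = sample.int(1e6, 1))$p_estimate
      se <- sqrt(exact * (1 - exact) / 10000)
      expect_lt(abs(mc - exact), max(3 * se, 3e-4))
    }
  })
})

test_that("data-frame interface matches the vector interface", {
  df <- sim_group_values(10, 12, "lognormal", shift = 10, seed = 21)
  r_df <- perm_mean_test(df, value, group, n_surrogates = 1000, seed = 5)
  r_vec <- perm_mean_test(df$value[df$group == "g1"],
                          df$value[df$group == "g2"],
                          n_surrogates = 1000, seed = 5)
  expect_equal(r_df$observed_delta, r_vec$observed_delta)
  expect_equal(r_df$p_estimate, r_vec$p_estimate)
  td <- tidy(r_df)
  expect_equal(td$p.value, r_df$p_estimate)
  expect_equal(glance(r_df)$n1, 10L)
})

test_that("KS comparison follows the ECDF definition", {
  expect_equal(ks_compare(c(1, 2, 3), c(1, 2, 3))$d_statistic, 0)
  expect_equal(ks_compare(c(1, 2, 3), c(4, 5, 6))$d_statistic, 1)
  expect_equal(ks_compare(c(1, 3), c(2, 4))$d_statistic, 0.5)
  expect_error(ks_compare(numeric(0), 1:3), "nonempty")

  # cross-check d against the reference implementation on random data
  withr::with_seed(31, {
    for (rep in 1:20) {
      a <- rnorm(sample(5:40, 1))
      b <- rnorm(sample(5:40, 1), mean = runif(1, 0, 2))
      ours <- ks_compare(a, b)
      ref <- suppressWarnings(stats::ks.test(a, b))
      expect_equal(ours$d_statistic, unname(ref$statistic))
    }
  })
})

test_that("normality gate takes the parametric branch only when all groups pass", {
  expect_equal(normality_gate(c(0.2, 0.6)), "parametric")
  expect_equal(normality_gate(c(0.2, 0.01)), "nonparametric")
  # strict: p exactly at alpha fails the "P > 0.05" rule
  expect_equal(normality_gate(c(0.05, 0.8)), "nonparametric")
  expect_error(normality_gate(numeric(0)), "at least one")
  expect_error(normality_gate(c(0.5, 1.2)), "\\[0, 1\\]")

  df <- sim_group_values(30, 30, "lognormal", seed = 3)
  sg <- shapiro_gate(df, value, group)
  expect_equal(nrow(sg$per_group), 2L)
  expect_equal(sg$branch,
               normality_gate(sg$per_group$shapiro_p))
  # heavily skewed lognormal samples should fail normality
  expect_equal(sg$branch, "nonparametric")
})
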