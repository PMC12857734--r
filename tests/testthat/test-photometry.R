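test_that("dF/F collapses to zero when the channels agree", {
  tr <- tibble::tibble(
    time_s = seq(0, 10, 0.1),
    f465 = 100 * exp(-seq(0, 10, 0.1) / 50),
    f405 = 100 * exp(-seq(0, 10, 0.1) / 50)
  )
  out <- photometry_dff(tr)
  expect_lt(max(abs(out$dff)), 1e-12)

  cst <- tibble::tibble(time_s = 0:10, f465 = 5, f405 = 5)
  expect_error(photometry_dff(cst), "constant")
})

test_that("dF/F is invariant under common channel rescaling", {
  tr <- sim_photometry(60, fs_hz = 20, event_times_s = c(20, 40),
                       noise_sd = 0.3, motion_sd = 0.5, seed = 12)
  d1 <- photometry_dff(tr)$dff
  tr2 <- dplyr::mutate(tr, f465 = f465 * 3.7, f405 = f405 * 3.7)
  d2 <- photometry_dff(tr2)$dff
  expect_equal(d1, d2, tolerance = 1e-9)
})

test_that("dF/F recovers the injected transient peak", {
  tr <- sim_photometry(60, fs_hz = 20, event_times_s = 30, amplitude = 0.05,
                       tau_rise_s = 0.2, tau_decay_s = 1.5,
                       noise_sd = 0, motion_sd = 0, seed = 2)
  out <- photometry_dff(tr)
  lag <- attr(tr, "kernel_peak_lag_s")
  peak_t <- out$time_s[which.max(out$dff)]
  expect_lt(abs(peak_t - (30 + lag)), 2 / 20 + 1e-9)
})

test_that("baseline z-scoring centers and scales exactly", {
  tr <- photometry_dff(sim_photometry(60, fs_hz = 20, event_times_s = 40,
                                      noise_sd = 0.3, seed = 6))
  z <- zscore_trace(tr, baseline_window_s = c(0, 20))
  base <- z$zscore[z$time_s >= 0 & z$time_s <= 20]
  expect_lt(abs(mean(base)), 1e-9)
  expect_lt(abs(sd(base) - 1), 1e-9)

  # location invariance: shifting dff by a constant leaves z unchanged
  tr_shift <- dplyr::mutate(tr, dff = dff + 0.123)
  z2 <- zscore_trace(tr_shift, baseline_window_s = c(0, 20))
  expect_equal(z$zscore, z2$zscore, tolerance = 1e-12)

  # a sample at the baseline mean maps to z = 0
  i <- which.min(abs(tr$dff - mean(tr$dff[tr$time_s <= 20])))
  expect_lt(abs(z$zscore[i]),
            abs(tr$dff[i] - mean(tr$dff[tr$time_s <= 20])) / sd(tr$dff[tr$time_s <= 20]) + 1e-9)

  expect_error(zscore_trace(tr, c(50, 70)), "outside")
  expect_error(zscore_trace(tr, c(10, 10.1)), "fewer than 10")
  cst <- tibble::tibble(time_s = seq(0, 5, 0.1), dff = 1)
  expect_error(zscore_trace(cst, c(0, 5)), "variance")
})

test_that("peri-event rows have the documented length and alignment", {
  tr <- photometry_dff(sim_photometry(200, fs_hz = 10, event_times_s = 100,
                                      noise_sd = 0.2, seed = 3))
  pem <- peri_event_matrix(tr, 100, window_s = c(5, 10))
  expect_equal(nrow(pem), 151L) # 95..110 s at 10 Hz
  expect_equal(min(pem$time_rel_s), -5)
  expect_equal(max(pem$time_rel_s), 10)
  expect_equal(sum(pem$time_rel_s == 0), 1L)

  # two identical events give two identical rows
  pem2 <- peri_event_matrix(tr, c(100, 100), window_s = c(5, 10))
  z1 <- pem2$zscore[pem2$event_id == 1]
  z2 <- pem2$zscore[pem2$event_id == 2]
  expect_identical(z1, z2)

  # edge events are dropped with a warning, never padded
  expect_warning(
    pem3 <- peri_event_matrix(tr, c(2, 100), window_s = c(5, 10)),
    "dropped"
  )
  expect_equal(unique(pem3$event_id), 2L)
  expect_error(
    suppressWarnings(peri_event_matrix(tr, 2, window_s = c(5, 10))),
    "no events"
  )
})

test_that("binned AUC is a left-Riemann sum and additive over bins", {
  tb <- tibble::tibble(time_s = seq(0, 4.9, 0.1), zscore = 2)
  out <- binned_auc(tb, bin_s = 5)
  expect_equal(nrow(out), 1L)
  expect_equal(out$auc_z_s, 10.0)
  expect_false(out$partial)

  # z == 0 gives all-zero bins
  tb0 <- tibble::tibble(time_s = seq(0, 9.9, 0.1), zscore = 0)
  expect_true(all(binned_auc(tb0, 5)$auc_z_s == 0))

  # splitting 10 s into 5 + 5 preserves the total
  withr::with_seed(4, {
    z <- rnorm(100)
    tb <- tibble::tibble(time_s = seq(0, 9.9, 0.1), zscore = z)
    whole <- binned_auc(tb, bin_s = 10)$auc_z_s
    parts <- binned_auc(tb, bin_s = 5)$auc_z_s
    expect_equal(sum(parts), whole, tolerance = 1e-12)
  })

  # a trailing sample beyond the last full bin is flagged partial
  tb <- tibble::tibble(time_s = seq(0, 5, 0.1), zscore = 1)
  out <- binned_auc(tb, 5)
  expect_equal(out$partial, c(FALSE, TRUE))

  expect_error(binned_auc(tibble::tibble()), "nonempty")
})

test_that("event-adjacent bin carries the largest AUC at moderate SNR", {
  # 40 runs here; the 200-run >=95% check lives in the acceptance suite
  hits <- vapply(1:40, function(i) {
    tr <- sim_photometry(60, fs_hz = 20, event_times_s = 30,
                         amplitude = 0.05, noise_sd = 1.2, f0 = 100,
                         seed = 5000 + i)
    pem <- peri_event_matrix(photometry_dff(tr), 30, window_s = c(5, 10))
    auc <- binned_auc(pem, bin_s = 5)
    best <- auc$bin_start_s[which.max(auc$auc_z_s)]
    best %in% c(0, 5)
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})
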