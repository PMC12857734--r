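test_that("bursty-train simulator is deterministic and validates its spec", {
  a <- sim_bursty_train(120, 1, 0.5, seed = 5)
  b <- sim_bursty_train(120, 1, 0.5, seed = 5)
  expect_identical(a, b)
  c <- sim_bursty_train(120, 1, 0.5, seed = 6)
  expect_false(identical(a$spike_time_s, c$spike_time_s))

  expect_error(sim_bursty_train(120, 1, 1.5, seed = 1), "p_burst")
  expect_error(sim_bursty_train(120, 1, 0.5, intra_burst_isi_ms = 80, seed = 1),
               "intra_burst_isi_ms")
  expect_error(sim_bursty_train(120, 1, 0.5, min_inter_event_gap_ms = 160,
                                seed = 1), "min_inter_event_gap_ms")
  expect_error(sim_bursty_train(-1, 1, 0.5, seed = 1), "duration_s")
  expect_error(sim_bursty_train(120, 1, 0.5, spikes_per_burst = 1, seed = 1),
               "spikes_per_burst")
})

test_that("generated bursts are exactly the detected bursts", {
  withr::with_seed(3, {
    for (rep in 1:100) {
      tr <- sim_bursty_train(
        duration_s = runif(1, 30, 120),
        rate_events_hz = runif(1, 0.3, 3),
        p_burst = runif(1),
        spikes_per_burst = sample(2:6, 1),
        intra_burst_isi_ms = runif(1, 5, 79),
        min_inter_event_gap_ms = runif(1, 161, 400),
        seed = sample.int(1e6, 1)
      )
      det <- detect_bursts(tr$spike_time_s)
      truth <- attr(tr, "true_bursts")
      expect_equal(nrow(det), nrow(truth))
      if (nrow(truth) > 0) {
        expect_equal(det$first_spike, truth$first_spike)
        expect_equal(det$last_spike, truth$last_spike)
      }
      # and the detected %SWB equals the generated label fraction exactly
      s <- burst_stats(tr$spike_time_s, attr(tr, "duration_s"))
      expect_equal(s$swb_percent,
                   if (nrow(tr)) 100 * mean(tr$in_burst) else 0)
    }
  })
})

test_that("detected %SWB matches the closed-form expectation on average", {
  # E[%SWB] = 100 p k / (p k + 1 - p); 60 realizations here, the full
  # 200-run check lives in the acceptance suite
  p <- 0.5
  k <- 3
  swb <- vapply(1:60, function(i) {
    tr <- sim_bursty_train(300, 1.5, p, spikes_per_burst = k, seed = 1000 + i)
    burst_stats(tr$spike_time_s, 300)$swb_percent
  }, numeric(1))
  expect_lt(abs(mean(swb) - expected_swb(p, k)), 2)
})

test_that("p_burst = 0 yields no detected bursts; p_burst = 1 yields 100%", {
  tr0 <- sim_bursty_train(120, 1, 0, seed = 2)
  expect_equal(burst_stats(tr0$spike_time_s, 120)$swb_percent, 0)
  tr1 <- sim_bursty_train(120, 1, 1, seed = 2)
  expect_equal(burst_stats(tr1$spike_time_s, 120)$swb_percent, 100)
})

test_that("group-value simulator hits the lognormal mean and builds a null", {
  spec <- list(meanlog = 3, sdlog = 0.6)
  g <- sim_group_values(4000, 4000, "lognormal", shift = 0, params = spec,
                        seed = 9)
  mu <- exp(spec$meanlog + spec$sdlog^2 / 2)
  sd_ln <- sqrt((exp(spec$sdlog^2) - 1)) * mu
  se <- sd_ln / sqrt(4000)
  expect_lt(abs(mean(g$value[g$group == "g1"]) - mu), 3 * se)
  expect_lt(abs(mean(g$value[g$group == "g2"]) - mu), 3 * se)

  # shift moves group 2 by exactly that amount in expectation
  gs <- sim_group_values(4000, 4000, "lognormal", shift = 5, params = spec,
                         seed = 9)
  expect_equal(gs$value[gs$group == "g2"] - g$value[g$group == "g2"],
               rep(5, 4000))

  expect_identical(sim_group_values(10, 10, "beta", seed = 1),
                   sim_group_values(10, 10, "beta", seed = 1))
  expect_error(sim_group_values(1, 5, seed = 1), "n1")
  expect_error(sim_group_values(5, 5, family = "gamma", seed = 1))
})

test_that("photometry simulator degenerates to the pure bleach curve", {
  tr <- sim_photometry(20, fs_hz = 20, event_times_s = 10, amplitude = 0,
                       noise_sd = 0, motion_sd = 0, f0 = 100,
                       bleach_tau_s = 300, seed = 1)
  bleach <- 100 * exp(-tr$time_s / 300)
  expect_equal(tr$f465, bleach)
  expect_equal(tr$f405, bleach)
})

test_that("photometry simulator peaks at the analytic kernel lag", {
  tau_r <- 0.2
  tau_d <- 1.5
  tr <- sim_photometry(40, fs_hz = 100, event_times_s = 10, amplitude = 0.05,
                       tau_rise_s = tau_r, tau_decay_s = tau_d,
                       noise_sd = 0, motion_sd = 0, seed = 1)
  lag <- log(tau_d / tau_r) * tau_r * tau_d / (tau_d - tau_r)
  expect_equal(attr(tr, "kernel_peak_lag_s"), lag)
  peak_t <- tr$time_s[which.max(attr(tr, "true_dff"))]
  expect_lt(abs(peak_t - (10 + lag)), 2 / 100)
  # unit-peak normalization: max true dff equals the amplitude
  expect_equal(max(attr(tr, "true_dff")), 0.05, tolerance = 1e-3)

  expect_identical(sim_photometry(10, seed = 3), sim_photometry(10, seed = 3))
  expect_error(sim_photometry(10, event_times_s = c(5, 5), seed = 1),
               "strictly increasing")
  expect_error(sim_photometry(10, event_times_s = 12, seed = 1), "within")
  expect_error(sim_photometry(10, tau_rise_s = 2, tau_decay_s = 1, seed = 1),
               "tau_decay_s")
})

test_that("spine-table simulator keeps ground truth unambiguous", {
  s <- sim_spine_table(500, p_mushroom = 1, mushroom_mean_nm = 600,
                       mushroom_sd_nm = 30, seed = 4)
  expect_true(all(classify_spines(s)$class == "mushroom"))

  s0 <- sim_spine_table(0, seed = 1)
  expect_equal(nrow(s0), 0L)

  expect_error(
    sim_spine_table(100, thin_mean_nm = 340, thin_sd_nm = 50, seed = 1),
    "straddles"
  )
  expect_identical(sim_spine_table(50, seed = 8), sim_spine_table(50, seed = 8))
})
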