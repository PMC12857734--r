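#' Simulate a bursty spike train with exact ground truth
#'
#' Generates a renewal-style event stream in which each event is either a
#' burst of `spikes_per_burst` spikes at a fixed short intra-burst ISI, or
#' a single spike. Inter-event gaps (last spike of one event to first
#' spike of the next) are exponential with mean `1 / rate_events_hz`,
#' left-truncated at `min_inter_event_gap_ms`. Because intra-burst ISIs
#' must be below the 80 ms onset threshold and inter-event gaps above the
#' 160 ms termination threshold, the generated bursts are exactly the
#' bursts [detect_bursts()] finds: ground truth is recoverable with zero
#' ambiguity. The expected %SWB is
#' `100 * p * k / (p * k + 1 - p)` for burst probability `p` and burst
#' size `k`.
#'
#' @param duration_s Recording length in seconds.
#' @param rate_events_hz Mean event rate (bursts and singlets combined),
#'   events per second.
#' @param p_burst Probability that an event is a burst, in \[0, 1\].
#' @param spikes_per_burst Spikes per burst, integer >= 2.
#' @param intra_burst_isi_ms ISI inside a burst; must be < 80 ms.
#' @param min_inter_event_gap_ms Floor on inter-event gaps; must be
#'   > 160 ms.
#' @param seed Integer seed; equal arguments and seed give identical
#'   output.
#' @param neuron_id Optional identifier attached to the output.
#' @return A tibble with one row per spike: `neuron_id` (if given),
#'   `spike_time_s`, `event_id`, `in_burst` (ground-truth label).
#'   Attributes: `duration_s`, `expected_swb_percent`, and `true_bursts`
#'   (tibble of ground-truth burst spike-index ranges).
#' @examples
#' tr <- sim_bursty_train(duration_s = 60, rate_events_hz = 1,
#'                        p_burst = 0.5, seed = 1)
#' attr(tr, "expected_swb_percent")
#' @export
sim_bursty_train <- function(duration_s, rate_events_hz = 1, p_burst = 0.3,
                             spikes_per_burst = 3, intra_burst_isi_ms = 40,
                             min_inter_event_gap_ms = 200, seed,
                             neuron_id = NULL) {
  .check_number(duration_s, "duration_s", lower = 0, strict_lower = TRUE)
  .check_number(rate_events_hz, "rate_events_hz", lower = 0, strict_lower = TRUE)
  .check_number(p_burst, "p_burst", lower = 0, upper = 1)
  .check_number(spikes_per_burst, "spikes_per_burst", lower = 2)
  .check_number(intra_burst_isi_ms, "intra_burst_isi_ms", lower = 0,
                upper = 80, strict_lower = TRUE, strict_upper = TRUE)
  .check_number(min_inter_event_gap_ms, "min_inter_event_gap_ms",
                lower = 160, strict_lower = TRUE)
  seed <- .check_seed(seed)
  k <- as.integer(spikes_per_burst)
  isi_s <- intra_burst_isi_ms / 1e3
  min_gap_s <- min_inter_event_gap_ms / 1e3

  out <- withr::with_seed(seed, {
    times <- numeric(0)
    event_id <- integer(0)
    in_burst <- logical(0)
    t_now <- runif(1, 0, min(1, duration_s)) # random start phase
    ev <- 0L
    repeat {
      if (t_now > duration_s) break
      ev <- ev + 1L
      is_b <- runif(1) < p_burst
      ts <- if (is_b) t_now + isi_s * (seq_len(k) - 1L) else t_now
      if (max(ts) > duration_s) break # drop events truncated by the edge
      times <- c(times, ts)
      event_id <- c(event_id, rep(ev, length(ts)))
      in_burst <- c(in_burst, rep(is_b, length(ts)))
      # left-truncated exponential gap: memorylessness makes this exact
      gap <- min_gap_s + rexp(1, rate_events_hz)
      t_now <- max(ts) + gap
    }
    tibble(spike_time_s = times, event_id = event_id, in_burst = in_burst)
  })
  if (!is.null(neuron_id)) {
    out <- tibble(neuron_id = neuron_id, out)
  }
  true_bursts <- if (any(out$in_burst)) {
    out |>
      mutate(idx = dplyr::row_number()) |>
      filter(.data$in_burst) |>
      group_by(.data$event_id) |>
      summarise(first_spike = as.integer(min(.data$idx)),
                last_spike = as.integer(max(.data$idx)),
                n_spikes = as.integer(dplyr::n()), .groups = "drop") |>
      select(-"event_id")
  } else {
    tibble(first_spike = integer(), last_spike = integer(),
           n_spikes = integer())
  }
  attr(out, "duration_s") <- duration_s
  attr(out, "expected_swb_percent") <-
    100 * p_burst * k / (p_burst * k + 1 - p_burst)
  attr(out, "true_bursts") <- true_bursts
  attr(out, "seed") <- seed
  class(out) <- c("da_sim_train", class(out))
  out
}

#' Simulate two groups of per-neuron statistic values
#'
#' Draws two vectors of per-neuron statistic values (firing rate, %SWB, or
#' any scalar endpoint) from a common family, with an additive location
#' shift applied to the second group. The lognormal family emulates the
#' right-skewed, non-normal per-neuron distributions that motivate the
#' permutation test; beta and normal families are available for bounded
#' and symmetric cases.
#'
#' @param n1,n2 Group sizes (>= 2).
#' @param family `"lognormal"` (params `meanlog`, `sdlog`), `"beta"`
#'   (params `shape1`, `shape2`), or `"normal"` (params `mean`, `sd`).
#' @param shift Additive shift of group 2 relative to group 1, in the
#'   units of the statistic (0 = null case).
#' @param params Named list of family parameters (defaults:
#'   lognormal meanlog 3, sdlog 0.6; beta shape1 2, shape2 5;
#'   normal mean 0, sd 1).
#' @param seed Integer seed.
#' @return A tibble with columns `group` (`"g1"`/`"g2"`), `neuron_id`,
#'   `value`.
#' @examples
#' sim_group_values(5, 5, family = "lognormal", shift = 0, seed = 1)
#' @export
sim_group_values <- function(n1, n2, family = c("lognormal", "beta", "normal"),
                             shift = 0, params = list(), seed) {
  family <- match.arg(family)
  .check_number(n1, "n1", lower = 2)
  .check_number(n2, "n2", lower = 2)
  .check_number(shift, "shift")
  seed <- .check_seed(seed)
  draw <- switch(family,
    lognormal = {
      meanlog <- params$meanlog %||% 3
      sdlog <- params$sdlog %||% 0.6
      .check_number(sdlog, "sdlog", lower = 0, strict_lower = TRUE)
      function(n) rlnorm(n, meanlog, sdlog)
    },
    beta = {
      s1 <- params$shape1 %||% 2
      s2 <- params$shape2 %||% 5
      .check_number(s1, "shape1", lower = 0, strict_lower = TRUE)
      .check_number(s2, "shape2", lower = 0, strict_lower = TRUE)
      function(n) rbeta(n, s1, s2)
    },
    normal = {
      m <- params$mean %||% 0
      s <- params$sd %||% 1
      .check_number(s, "sd", lower = 0, strict_lower = TRUE)
      function(n) rnorm(n, m, s)
    }
  )
  withr::with_seed(seed, {
    tibble(
      group = rep(c("g1", "g2"), c(n1, n2)),
      neuron_id = c(paste0("g1_", seq_len(n1)), paste0("g2_", seq_len(n2))),
      value = c(draw(n1), draw(n2) + shift)
    )
  })
}
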