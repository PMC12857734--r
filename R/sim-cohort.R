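#' Simulate a cohort of bursty neurons with matching feature table
#'
#' Builds a multi-neuron spike table plus the waveform-feature table the
#' inclusion gate reads, for one experimental group. Each neuron is an
#' independent [sim_bursty_train()] draw (per-neuron seeds derived from
#' `seed`), and its feature row reports the realized mean rate together
#' with waveform values that satisfy the dopamine-neuron criteria, so the
#' whole cohort passes the gate unless you edit it.
#'
#' @param n_neurons Number of neurons.
#' @param group Group label attached to every feature row.
#' @param duration_s Per-neuron recording duration (s).
#' @inheritParams sim_bursty_train
#' @return A list with `spikes` (neuron_id, spike_time_s), `features`
#'   (neuron_id, group, triphasic, duration_ms, start_to_trough_ms,
#'   mean_rate_hz), `truth` (per-neuron tibble with true %SWB and the
#'   generator expectation), `duration_s`.
#' @examples
#' coh <- sim_cohort(3, group = "sham", duration_s = 120, seed = 1)
#' @export
sim_cohort <- function(n_neurons, group, duration_s = 600,
                       rate_events_hz = 1, p_burst = 0.3,
                       spikes_per_burst = 3, intra_burst_isi_ms = 40,
                       min_inter_event_gap_ms = 200, seed) {
  .check_number(n_neurons, "n_neurons", lower = 1)
  seed <- .check_seed(seed)
  ids <- sprintf("%s_n%03d", group, seq_len(n_neurons))
  trains <- purrr::imap(ids, function(id, i) {
    sim_bursty_train(
      duration_s = duration_s, rate_events_hz = rate_events_hz,
      p_burst = p_burst, spikes_per_burst = spikes_per_burst,
      intra_burst_isi_ms = intra_burst_isi_ms,
      min_inter_event_gap_ms = min_inter_event_gap_ms,
      seed = (seed + 7919 * i) %% 2147483647, neuron_id = id
    )
  })
  spikes <- bind_rows(lapply(trains, function(tr) {
    tibble(neuron_id = tr$neuron_id, spike_time_s = tr$spike_time_s)
  }))
  truth <- bind_rows(lapply(trains, function(tr) {
    tibble(
      neuron_id = tr$neuron_id[1],
      n_spikes = nrow(tr),
      true_swb_percent = if (nrow(tr)) 100 * mean(tr$in_burst) else 0,
      expected_swb_percent = attr(tr, "expected_swb_percent")
    )
  }))
  features <- truth |>
    mutate(
      group = group,
      triphasic = TRUE,
      duration_ms = 2.5,
      start_to_trough_ms = 1.3,
      mean_rate_hz = .data$n_spikes / duration_s
    ) |>
    select("neuron_id", "group", "triphasic", "duration_ms",
           "start_to_trough_ms", "mean_rate_hz")
  list(spikes = spikes, features = features, truth = truth,
       duration_s = duration_s)
}

#' Combine two simulated cohorts
#'
#' @param a,b Results of [sim_cohort()] with equal `duration_s`.
#' @return A list with the same shape, rows stacked.
#' @export
bind_cohorts <- function(a, b) {
  if (!isTRUE(all.equal(a$duration_s, b$duration_s))) {
    abort("cohorts must share duration_s.")
  }
  list(
    spikes = bind_rows(a$spikes, b$spikes),
    features = bind_rows(a$features, b$features),
    truth = bind_rows(a$truth, b$truth),
    duration_s = a$duration_s
  )
}
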