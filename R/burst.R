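#' Detect bursts in a spike train (two-threshold Grace rule)
#'
#' A burst opens at the first of two consecutive spikes whose interspike
#' interval (ISI) is strictly shorter than `onset_isi_max_ms`; subsequent
#' spikes are appended while the next ISI is at most
#' `continuation_isi_max_ms`; the burst closes at the first ISI strictly
#' longer than that, or at the end of the train. Every spike belongs to at
#' most one burst and scanning resumes after a closed burst, so bursts are
#' disjoint and ordered. The 80--160 ms band therefore continues a burst
#' but can never open one.
#'
#' Comparisons are done in integer microseconds so that a spike pair at
#' exactly 80 ms never opens a burst and an ISI at exactly 160 ms always
#' continues one, independent of floating-point representation.
#'
#' @param spikes Numeric vector of spike times in seconds (strictly
#'   increasing), or a data frame with a `spike_time_s` column.
#' @param onset_isi_max_ms Onset threshold; a burst opens on an ISI
#'   strictly below this (default 80 ms).
#' @param continuation_isi_max_ms Continuation threshold; a burst keeps
#'   going while ISIs are `<=` this, and terminates on an ISI strictly
#'   above it (default 160 ms).
#' @return A tibble with one row per burst: `burst_id`, `first_spike`,
#'   `last_spike` (1-based inclusive spike indices), `n_spikes`,
#'   `start_s`, `end_s`.
#' @examples
#' detect_bursts(c(0, 0.05, 0.1, 0.5))
#' @export
detect_bursts <- function(spikes, onset_isi_max_ms = 80,
                          continuation_isi_max_ms = 160) {
  t_s <- .spike_vector(spikes)
  .check_number(onset_isi_max_ms, "onset_isi_max_ms", lower = 0,
                strict_lower = TRUE)
  .check_number(continuation_isi_max_ms, "continuation_isi_max_ms",
                lower = onset_isi_max_ms, strict_lower = TRUE)
  empty <- tibble(
    burst_id = integer(), first_spike = integer(), last_spike = integer(),
    n_spikes = integer(), start_s = numeric(), end_s = numeric()
  )
  n <- length(t_s)
  if (n < 2L) return(empty)

  isi_us <- diff(.times_to_us(t_s))
  onset_us <- round(onset_isi_max_ms * 1e3)
  cont_us <- round(continuation_isi_max_ms * 1e3)

  first <- integer(0)
  last <- integer(0)
  i <- 1L
  while (i <= n - 1L) {
    if (isi_us[i] < onset_us) {
      start <- i
      j <- i + 1L
      while (j <= n - 1L && isi_us[j] <= cont_us) j <- j + 1L
      first <- c(first, start)
      last <- c(last, j)
      i <- j + 1L # scanning resumes after the burst's last spike
    } else {
      i <- i + 1L
    }
  }
  if (length(first) == 0L) return(empty)
  tibble(
    burst_id = seq_along(first),
    first_spike = first,
    last_spike = last,
    n_spikes = last - first + 1L,
    start_s = t_s[first],
    end_s = t_s[last]
  )
}

.burst_stats_one <- function(t_s, duration_s, onset_isi_max_ms,
                             continuation_isi_max_ms) {
  .check_number(duration_s, "duration_s", lower = 0, strict_lower = TRUE)
  if (length(t_s) > 0 && (min(t_s) < 0 || max(t_s) > duration_s)) {
    abort("spike times must lie within [0, duration_s].")
  }
  bursts <- detect_bursts(t_s, onset_isi_max_ms, continuation_isi_max_ms)
  n <- length(t_s)
  in_burst <- sum(bursts$n_spikes)
  tibble(
    n_spikes = n,
    firing_rate_hz = n / duration_s,
    n_bursts = nrow(bursts),
    spikes_in_bursts = in_burst,
    swb_percent = if (n == 0L) 0 else 100 * in_burst / n
  )
}

#' Per-neuron firing rate and percent spikes within bursts (%SWB)
#'
#' Computes, for each neuron, the mean firing rate (spikes / recording
#' duration) and %SWB: the number of spikes inside detected bursts divided
#' by the total number of spikes, times 100. An empty train has rate 0 and
#' %SWB 0.
#'
#' @param spikes Numeric vector of spike times (one neuron), or a data
#'   frame with columns `spike_time_s` and optionally `neuron_id`.
#' @param duration_s Recording duration in seconds. Either a single value
#'   applied to all neurons, or a data frame with columns `neuron_id`,
#'   `duration_s`.
#' @inheritParams detect_bursts
#' @return A tibble with one row per neuron: `neuron_id` (if present),
#'   `n_spikes`, `firing_rate_hz`, `n_bursts`, `spikes_in_bursts`,
#'   `swb_percent`.
#' @examples
#' burst_stats(c(0, 0.05, 0.1, 0.5), duration_s = 10)
#' @export
burst_stats <- function(spikes, duration_s, onset_isi_max_ms = 80,
                        continuation_isi_max_ms = 160) {
  if (!is.data.frame(spikes)) {
    t_s <- .spike_vector(spikes)
    return(.burst_stats_one(t_s, duration_s, onset_isi_max_ms,
                            continuation_isi_max_ms))
  }
  if (!"spike_time_s" %in% names(spikes)) {
    abort("`spikes` needs a `spike_time_s` column.")
  }
  if (!"neuron_id" %in% names(spikes)) {
    return(.burst_stats_one(.spike_vector(spikes), duration_s,
                            onset_isi_max_ms, continuation_isi_max_ms))
  }
  dur_tbl <- if (is.data.frame(duration_s)) {
    duration_s
  } else {
    tibble(neuron_id = unique(spikes$neuron_id), duration_s = duration_s)
  }
  spikes |>
    arrange(.data$neuron_id, .data$spike_time_s) |>
    group_by(.data$neuron_id) |>
    dplyr::group_modify(function(df, key) {
      dur <- dur_tbl$duration_s[match(key$neuron_id, dur_tbl$neuron_id)]
      if (is.na(dur)) abort(sprintf("no duration for neuron '%s'", key$neuron_id))
      .burst_stats_one(.spike_vector(df$spike_time_s), dur,
                       onset_isi_max_ms, continuation_isi_max_ms)
    }) |>
    ungroup()
}
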