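#' Write a simulated cohort to disk
#'
#' Emits the same CSV dialect the analysis stages read — `spikes.csv`
#' (neuron_id, spike_time_s) and `features.csv` (neuron_id, group,
#' triphasic, duration_ms, start_to_trough_ms, mean_rate_hz) — plus a
#' `ground_truth.json` sidecar with the per-neuron true %SWB labels.
#'
#' @param cohort A [sim_cohort()] / [bind_cohorts()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written file paths.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    spikes = file.path(dir, "spikes.csv"),
    features = file.path(dir, "features.csv"),
    truth = file.path(dir, "ground_truth.json")
  )
  readr::write_csv(cohort$spikes, paths[["spikes"]])
  readr::write_csv(cohort$features, paths[["features"]])
  jsonlite::write_json(
    list(duration_s = cohort$duration_s, per_neuron = cohort$truth),
    paths[["truth"]], auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(paths)
}

#' Write a simulated photometry recording to disk
#'
#' Emits `trace.csv` (time_s, f465, f405), `events.csv` (event_time_s,
#' label) and a `ground_truth.json` sidecar with the kernel peak lag and
#' true event times.
#'
#' @param trace A [sim_photometry()] result.
#' @param dir Output directory.
#' @param labels Optional per-event labels (recycled); default `"all"`.
#' @return Invisibly, the written file paths.
#' @export
write_photometry <- function(trace, dir, labels = "all") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ev <- attr(trace, "event_times_s") %||% numeric(0)
  paths <- c(
    trace = file.path(dir, "trace.csv"),
    events = file.path(dir, "events.csv"),
    truth = file.path(dir, "ground_truth.json")
  )
  readr::write_csv(as_tibble(trace), paths[["trace"]])
  readr::write_csv(
    tibble(event_time_s = ev,
           label = rep_len(labels, length(ev))),
    paths[["events"]]
  )
  jsonlite::write_json(
    list(event_times_s = ev,
         kernel_peak_lag_s = attr(trace, "kernel_peak_lag_s"),
         fs_hz = attr(trace, "fs_hz"),
         seed = attr(trace, "seed")),
    paths[["truth"]], auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(paths)
}
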