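#' Build a run configuration
#'
#' Collects the inputs and parameters an end-to-end run needs. Inputs may
#' be file paths (CSV) or in-memory data frames; paths are resolved at run
#' time. The single `seed` feeds a deterministic per-stage derivation so
#' reruns with the same configuration are reproducible bit for bit.
#'
#' @param spikes,features Spike table (neuron_id, spike_time_s) and
#'   feature table (neuron_id, group, triphasic, duration_ms,
#'   start_to_trough_ms, mean_rate_hz); paths or data frames.
#' @param trace,events Photometry trace (time_s, f465, f405) and event
#'   table (event_time_s, label); paths or data frames.
#' @param duration_s Recording duration for the spike stage.
#' @param onset_isi_max_ms,continuation_isi_max_ms Burst thresholds.
#' @param n_surrogates Surrogates for every permutation test.
#' @param window_s Peri-event `c(pre, post)` window (s).
#' @param bin_s AUC bin width (s).
#' @param out_dir Output directory (`NULL`: return the report only).
#' @param seed Master seed.
#' @return A list of class `da_run_config`.
#' @export
run_config <- function(spikes = NULL, features = NULL, trace = NULL,
                       events = NULL, duration_s = NULL,
                       onset_isi_max_ms = 80, continuation_isi_max_ms = 160,
                       n_surrogates = 10000, window_s = c(5, 10), bin_s = 5,
                       out_dir = NULL, seed = 1) {
  cfg <- list(
    spikes = spikes, features = features, trace = trace, events = events,
    duration_s = duration_s, onset_isi_max_ms = onset_isi_max_ms,
    continuation_isi_max_ms = continuation_isi_max_ms,
    n_surrogates = n_surrogates, window_s = window_s, bin_s = bin_s,
    out_dir = out_dir, seed = .check_seed(seed)
  )
  structure(cfg, class = "da_run_config")
}

#' Read a run configuration from YAML
#'
#' @param path YAML file whose keys match [run_config()] arguments.
#' @return A `da_run_config`.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) {
    abort(paste0("unknown config keys: ", paste(bad, collapse = ", ")))
  }
  do.call(run_config, vals)
}

.load_table <- function(x, what) {
  if (is.null(x)) abort(sprintf("config is missing `%s`.", what))
  if (is.data.frame(x)) return(as_tibble(x))
  if (!is.character(x) || !file.exists(x)) {
    abort(sprintf("`%s` path does not exist: %s", what, x))
  }
  readr::read_csv(x, show_col_types = FALSE)
}

.config_hash <- function(config) {
  keep <- setdiff(names(config), "out_dir")
  rlang::hash(config[keep])
}

.write_report <- function(report, tables, out_dir, prefix) {
  if (is.null(out_dir)) return(invisible(NULL))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(
    report, file.path(out_dir, paste0(prefix, "_report.json")),
    auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null"
  )
  for (nm in names(tables)) {
    readr::write_csv(tables[[nm]],
                     file.path(out_dir, paste0(prefix, "_", nm, ".csv")))
  }
  invisible(NULL)
}

#' End-to-end two-group electrophysiology comparison
#'
#' Runs the whole spike-train pipeline: reads the spike and feature
#' tables, applies the dopamine-neuron inclusion gate (excluded neurons
#' are logged with their reasons, never analyzed), computes per-neuron
#' firing rate and %SWB, and compares the two groups — for each endpoint
#' separately — by a Kolmogorov-Smirnov distribution comparison and the
#' surrogate permutation test of the mean difference. Per-neuron values
#' are the units of analysis; spikes are never pooled across neurons.
#'
#' @param config A [run_config()] with `spikes`, `features`, `duration_s`
#'   set (and optionally burst thresholds, `n_surrogates`, `out_dir`,
#'   `seed`).
#' @return A list report (also written as JSON + CSV under `out_dir` when
#'   set): `config_hash`, `seed`, `n_included`/`n_excluded` per group,
#'   `exclusions`, `per_neuron` tibble, and for each endpoint the KS
#'   result and the permutation-test summary. Errors if fewer than 2
#'   included neurons remain in either group.
#' @export
run_ephys_compare <- function(config) {
  stopifnot(inherits(config, "da_run_config"))
  spikes <- .load_table(config$spikes, "spikes")
  features <- .load_table(config$features, "features")
  if (!"group" %in% names(features)) {
    abort("feature table needs a `group` column with two levels.")
  }
  if (is.null(config$duration_s)) abort("config needs `duration_s`.")

  gated <- classify_da_neurons(features)
  exclusions <- gated |> filter(!.data$included) |>
    select("neuron_id", "group", "reasons")
  for (i in seq_len(nrow(exclusions))) {
    inform(sprintf("excluding neuron %s (%s): %s",
                   exclusions$neuron_id[i], exclusions$group[i],
                   exclusions$reasons[i]))
  }
  included <- gated |> filter(.data$included)
  lev <- unique(features$group)
  if (length(lev) != 2L) abort("`group` must have exactly two levels.")
  n_inc <- table(factor(included$group, levels = lev))
  if (any(n_inc < 2L)) {
    abort(sprintf(
      "fewer than 2 included neurons in group(s): %s",
      paste(lev[n_inc < 2L], collapse = ", ")
    ))
  }

  per_neuron <- spikes |>
    filter(.data$neuron_id %in% included$neuron_id) |>
    burst_stats(duration_s = config$duration_s,
                onset_isi_max_ms = config$onset_isi_max_ms,
                continuation_isi_max_ms = config$continuation_isi_max_ms) |>
    left_join(select(included, "neuron_id", "group"), by = "neuron_id")

  stat_seed <- derive_seed(config$seed, "stats")
  endpoint <- function(col, offset) {
    v <- per_neuron[[col]]
    g <- per_neuron$group
    ks <- ks_compare(v[g == lev[1]], v[g == lev[2]])
    pt <- perm_mean_test(v[g == lev[1]], v[g == lev[2]],
                         n_surrogates = config$n_surrogates,
                         seed = (stat_seed + offset) %% 2147483647)
    list(
      ks = as.list(ks),
      permutation = list(
        observed_delta = pt$observed_delta,
        exceedance_count = pt$exceedance_count,
        n_surrogates = pt$n_surrogates,
        p_estimate = pt$p_estimate,
        stars = pt$stars,
        seed = pt$seed,
        method = pt$method
      )
    )
  }

  report <- list(
    stage = "ephys_compare",
    config_hash = .config_hash(config),
    seed = config$seed,
    groups = as.character(lev),
    n_included = as.list(stats::setNames(as.integer(n_inc), lev)),
    n_excluded = nrow(exclusions),
    exclusions = exclusions,
    firing_rate = endpoint("firing_rate_hz", 1L),
    swb = endpoint("swb_percent", 2L)
  )
  .write_report(
    report[setdiff(names(report), c("exclusions"))],
    list(per_neuron = per_neuron, exclusions = exclusions),
    config$out_dir, "ephys"
  )
  report$per_neuron <- per_neuron
  invisible(report)
}

#' End-to-end photometry quantification
#'
#' Reads a dual-channel trace and an event table, computes dF/F via the
#' isosbestic affine fit, aligns peri-event windows (each row z-scored
#' against its own pre-event span), integrates the z-score over fixed
#' bins, and — when the event table carries two labels — compares the two
#' groups bin by bin with the surrogate permutation test. Events whose
#' windows overrun the recording are dropped and counted in the report.
#'
#' @param config A [run_config()] with `trace`, `events` set (and
#'   optionally `window_s`, `bin_s`, `n_surrogates`, `out_dir`, `seed`).
#' @return A list report (also written when `out_dir` is set):
#'   `config_hash`, `seed`, `n_events_used`/`n_events_dropped`,
#'   `auc_by_event` tibble, `mean_trace` tibble (per label), and
#'   `bin_tests` (per-bin permutation results, two-label input only).
#' @export
run_photometry_quant <- function(config) {
  stopifnot(inherits(config, "da_run_config"))
  trace <- .load_table(config$trace, "trace")
  events <- .load_table(config$events, "events")
  if (!"event_time_s" %in% names(events)) {
    abort("event table needs an `event_time_s` column.")
  }
  if (!"label" %in% names(events)) events$label <- "all"
  events <- arrange(events, .data$event_time_s)

  proc <- photometry_dff(trace)
  pem <- peri_event_matrix(proc, events$event_time_s,
                           window_s = config$window_s, baseline = "pre")
  kept <- unique(pem$event_id)
  ev_used <- events[kept, , drop = FALSE] |>
    mutate(event_id = kept)

  auc <- binned_auc(pem, bin_s = config$bin_s) |>
    left_join(select(ev_used, "event_id", "label"), by = "event_id")
  mean_trace <- pem |>
    left_join(select(ev_used, "event_id", "label"), by = "event_id") |>
    group_by(.data$label, .data$time_rel_s) |>
    summarise(mean_z = mean(.data$zscore),
              sem_z = sd(.data$zscore) / sqrt(dplyr::n()),
              .groups = "drop")

  lev <- unique(ev_used$label)
  bin_tests <- NULL
  if (length(lev) == 2L) {
    stat_seed <- derive_seed(config$seed, "photometry")
    bin_tests <- auc |>
      filter(!.data$partial) |>
      group_by(.data$bin_start_s, .data$bin_end_s) |>
      dplyr::group_modify(function(df, key) {
        a <- df$auc_z_s[df$label == lev[1]]
        b <- df$auc_z_s[df$label == lev[2]]
        if (length(a) < 2L || length(b) < 2L) {
          return(tibble(observed_delta = NA_real_, exceedance_count = NA_integer_,
                        p_estimate = NA_real_, stars = NA_character_))
        }
        s <- (stat_seed + round(key$bin_start_s * 1000)) %% 2147483647
        pt <- perm_mean_test(a, b, n_surrogates = config$n_surrogates,
                             seed = s)
        tibble(observed_delta = pt$observed_delta,
               exceedance_count = pt$exceedance_count,
               p_estimate = pt$p_estimate, stars = pt$stars)
      }) |>
      ungroup()
  }

  report <- list(
    stage = "photometry_quant",
    config_hash = .config_hash(config),
    seed = config$seed,
    window_s = config$window_s,
    bin_s = config$bin_s,
    n_surrogates = config$n_surrogates,
    n_events_used = length(kept),
    n_events_dropped = attr(pem, "n_dropped"),
    labels = as.character(lev)
  )
  tables <- list(auc_by_event = auc, mean_trace = mean_trace)
  if (!is.null(bin_tests)) tables$bin_tests <- bin_tests
  .write_report(c(report, list(bin_tests = bin_tests)), tables,
                config$out_dir, "photometry")
  c(report, list(auc_by_event = auc, mean_trace = mean_trace,
                 bin_tests = bin_tests))
}
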