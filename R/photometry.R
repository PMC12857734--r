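#' Isosbestic correction and dF/F
#'
#' Fits the reference (405 nm) channel onto the signal (465 nm) channel by
#' ordinary least squares (slope + intercept), giving a fitted reference
#' `r(t)` that carries the bleaching and motion components the two
#' channels share; the fractional fluorescence change is then
#' `dff = (f465 - r) / r`. The affine fit makes dff invariant under a
#' common multiplicative rescaling of both channels and tolerant of
#' channel-specific offsets.
#'
#' @param trace A data frame with columns `time_s`, `f465`, `f405` on a
#'   uniform, strictly increasing time grid.
#' @return The input as a tibble with a `dff` column added and attribute
#'   `fs_hz`. Errors if the reference channel has zero variance (the fit
#'   would be degenerate) or if the fitted reference crosses zero.
#' @examples
#' tr <- sim_photometry(duration_s = 30, fs_hz = 20, event_times_s = 10,
#'                      seed = 1)
#' head(photometry_dff(tr))
#' @export
photometry_dff <- function(trace) {
  trace <- .check_trace(trace)
  if (sd(trace$f405) == 0) {
    abort("reference channel f405 is constant; unusable for correction.")
  }
  fit <- lm(f465 ~ f405, data = trace)
  r <- fitted(fit)
  if (any(r <= 0)) {
    abort("fitted reference crosses zero; dF/F is undefined.")
  }
  trace$dff <- (trace$f465 - r) / r
  trace
}

.check_trace <- function(trace) {
  if (!is.data.frame(trace)) abort("`trace` must be a data frame.")
  need <- c("time_s", "f465", "f405")
  miss <- setdiff(need, names(trace))
  if (length(miss)) {
    abort(paste0("missing trace columns: ", paste(miss, collapse = ", ")))
  }
  if (nrow(trace) < 2L) abort("trace needs at least 2 samples.")
  dt <- diff(trace$time_s)
  if (any(dt <= 0)) abort("time must be strictly increasing.")
  if (max(dt) - min(dt) > 1e-6 * mean(dt) + 1e-12) {
    abort("time grid must be uniform.")
  }
  fs <- attr(trace, "fs_hz") %||% (1 / mean(dt))
  out <- as_tibble(trace)
  attr(out, "fs_hz") <- fs
  # carry simulator ground truth through if present
  for (a in c("event_times_s", "kernel_peak_lag_s", "true_dff")) {
    attr(out, a) <- attr(trace, a)
  }
  out
}

#' Baseline z-score of a dF/F trace
#'
#' Standardizes the whole dF/F series against a declared baseline window:
#' `z = (dff - mean_baseline) / sd_baseline`. Restricted to the baseline
#' window, the z series then has mean 0 and SD 1 by construction, and the
#' transform is invariant to adding a constant to dff everywhere.
#'
#' @param trace A data frame with columns `time_s` and `dff` (e.g. the
#'   output of [photometry_dff()]).
#' @param baseline_window_s Length-2 numeric `c(start, end)` in seconds;
#'   must lie inside the recording and contain at least 10 samples with
#'   nonzero variance.
#' @return The input tibble with a `zscore` column and attribute
#'   `baseline_window_s`.
#' @export
zscore_trace <- function(trace, baseline_window_s) {
  if (!is.data.frame(trace) || !all(c("time_s", "dff") %in% names(trace))) {
    abort("`trace` needs columns `time_s` and `dff`.")
  }
  if (length(baseline_window_s) != 2L ||
      baseline_window_s[1] >= baseline_window_s[2]) {
    abort("`baseline_window_s` must be c(start, end) with start < end.")
  }
  t <- trace$time_s
  if (baseline_window_s[1] < min(t) - 1e-9 ||
      baseline_window_s[2] > max(t) + 1e-9) {
    abort("baseline window lies outside the recording.")
  }
  in_base <- t >= baseline_window_s[1] & t <= baseline_window_s[2]
  if (sum(in_base) < 10L) abort("baseline window has fewer than 10 samples.")
  m <- mean(trace$dff[in_base])
  s <- sd(trace$dff[in_base])
  if (s == 0) abort("baseline dF/F variance is zero; cannot z-score.")
  out <- as_tibble(trace)
  out$zscore <- (out$dff - m) / s
  attr(out, "baseline_window_s") <- as.numeric(baseline_window_s)
  attr(out, "fs_hz") <- attr(trace, "fs_hz")
  out
}

#' Peri-event alignment of a processed trace
#'
#' Extracts, for each event, the samples from `pre` seconds before to
#' `post` seconds after its onset, time-aligned so 0 marks the onset.
#' Events whose window overruns either edge of the recording are dropped
#' with a warning. With `baseline = "pre"` (the default) each row is
#' z-scored against its own pre-event span — the convention behind
#' near-zero pre-event traces — using the raw `dff`; with
#' `baseline = "trace"` the trace-level `zscore` column (from
#' [zscore_trace()]) is used unchanged.
#'
#' @param trace A processed trace with `time_s` and `dff` (and `zscore` if
#'   `baseline = "trace"`).
#' @param event_times_s Sorted event onset times (s).
#' @param window_s Length-2 `c(pre, post)`, both > 0 seconds.
#' @param baseline `"pre"` or `"trace"` (see above).
#' @return A long tibble of class `da_peri_event` with columns `event_id`,
#'   `event_time_s`, `time_rel_s`, `zscore`; attributes `window_s`,
#'   `fs_hz`, `n_dropped`. One row block per surviving event, all blocks
#'   the same length.
#' @export
peri_event_matrix <- function(trace, event_times_s, window_s = c(5, 10),
                              baseline = c("pre", "trace")) {
  baseline <- match.arg(baseline)
  if (!is.data.frame(trace) || !all(c("time_s", "dff") %in% names(trace))) {
    abort("`trace` needs columns `time_s` and `dff`.")
  }
  if (baseline == "trace" && !"zscore" %in% names(trace)) {
    abort("baseline = \"trace\" needs a `zscore` column (run zscore_trace()).")
  }
  if (length(window_s) != 2L || any(window_s <= 0)) {
    abort("`window_s` must be c(pre, post), both > 0.")
  }
  ev <- as.numeric(event_times_s)
  if (is.unsorted(ev)) abort("event times must be sorted.")
  t <- trace$time_s
  fs <- attr(trace, "fs_hz") %||% (1 / mean(diff(t)))
  pre_n <- as.integer(round(window_s[1] * fs))
  post_n <- as.integer(round(window_s[2] * fs))

  rows <- list()
  dropped <- 0L
  for (i in seq_along(ev)) {
    ctr <- which.min(abs(t - ev[i]))
    lo <- ctr - pre_n
    hi <- ctr + post_n
    if (lo < 1L || hi > length(t)) {
      dropped <- dropped + 1L
      next
    }
    idx <- lo:hi
    val <- if (baseline == "trace") {
      trace$zscore[idx]
    } else {
      base <- trace$dff[lo:ctr] # the pre span, event sample included
      s <- sd(base)
      if (is.na(s) || s == 0) abort("pre-event baseline variance is zero.")
      (trace$dff[idx] - mean(base)) / s
    }
    rows[[length(rows) + 1L]] <- tibble(
      event_id = i,
      event_time_s = ev[i],
      time_rel_s = (idx - ctr) / fs,
      zscore = val
    )
  }
  if (dropped > 0L) {
    warn(sprintf("%d event(s) dropped: window overruns the recording edge.",
                 dropped))
  }
  if (length(rows) == 0L) abort("no events survive edge filtering.")
  out <- bind_rows(rows)
  attr(out, "window_s") <- as.numeric(window_s)
  attr(out, "fs_hz") <- fs
  attr(out, "n_dropped") <- dropped
  class(out) <- c("da_peri_event", class(out))
  out
}

#' Mean peri-event trace across events
#'
#' @param pem A [peri_event_matrix()] result.
#' @return A tibble `time_rel_s`, `mean_z`, `sem_z`, `n_events`.
#' @export
peri_event_mean <- function(pem) {
  if (!inherits(pem, "da_peri_event")) abort("`pem` must be a da_peri_event.")
  pem |>
    group_by(.data$time_rel_s) |>
    summarise(
      mean_z = mean(.data$zscore),
      sem_z = sd(.data$zscore) / sqrt(dplyr::n()),
      n_events = dplyr::n(),
      .groups = "drop"
    )
}

#' Binned area under the z-score curve
#'
#' Integrates the z-scored trace over contiguous fixed-width bins (default
#' 5 s) by a left-Riemann sum (`sum(z) * dt` per bin), which makes AUC
#' exactly additive over adjacent bins. Bins start at the beginning of the
#' window (`-pre` for peri-event input); a trailing bin not fully covered
#' by samples is kept but flagged `partial`.
#'
#' @param x A [peri_event_matrix()] result (binned per event), or a data
#'   frame with columns `time_rel_s` (or `time_s`) and `zscore`.
#' @param bin_s Bin width in seconds (default 5).
#' @return A tibble with `event_id` (peri-event input only), `bin_start_s`,
#'   `bin_end_s`, `auc_z_s`, `n_samples`, `partial`.
#' @examples
#' tb <- tibble::tibble(time_s = seq(0, 4.9, 0.1), zscore = 2)
#' binned_auc(tb) # one full bin, AUC = 10 z*s
#' @export
binned_auc <- function(x, bin_s = 5) {
  .check_number(bin_s, "bin_s", lower = 0, strict_lower = TRUE)
  if (!is.data.frame(x) || nrow(x) == 0L) abort("`x` must be a nonempty data frame.")
  tcol <- if ("time_rel_s" %in% names(x)) "time_rel_s" else "time_s"
  if (!tcol %in% names(x) || !"zscore" %in% names(x)) {
    abort("`x` needs a time column (`time_rel_s` or `time_s`) and `zscore`.")
  }
  one <- function(df) {
    t <- df[[tcol]]
    dt <- mean(diff(t))
    k <- floor((t - t[1]) / bin_s + 1e-9)
    full_n <- round(bin_s / dt)
    df |>
      mutate(.bin = k) |>
      group_by(.data$.bin) |>
      summarise(
        bin_start_s = t[1] + .data$.bin[1] * bin_s,
        bin_end_s = t[1] + (.data$.bin[1] + 1) * bin_s,
        auc_z_s = sum(.data$zscore) * dt,
        n_samples = dplyr::n(),
        .groups = "drop"
      ) |>
      mutate(partial = .data$n_samples < full_n) |>
      select(-".bin")
  }
  if (inherits(x, "da_peri_event")) {
    x |>
      group_by(.data$event_id) |>
      dplyr::group_modify(~ one(.x)) |>
      ungroup()
  } else {
    one(as_tibble(x))
  }
}
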