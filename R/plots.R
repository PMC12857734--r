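#' Plot a simulated or recorded spike train with its bursts
#'
#' Raster of spike times with detected bursts shaded, for a quick visual
#' check that the two-threshold rule behaves as expected on a train.
#'
#' @param object A `da_sim_train` (from [sim_bursty_train()]) or any data
#'   frame with a `spike_time_s` column.
#' @param ... Passed to [detect_bursts()] (threshold overrides).
#' @return A ggplot object.
#' @method autoplot da_sim_train
#' @export
autoplot.da_sim_train <- function(object, ...) {
  bursts <- detect_bursts(object$spike_time_s, ...)
  p <- ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = tibble(t = object$spike_time_s),
      ggplot2::aes(x = .data$t, xend = .data$t, y = 0, yend = 1),
      linewidth = 0.3
    ) +
    ggplot2::labs(x = "time (s)", y = NULL,
                  title = "spike train with detected bursts") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
  if (nrow(bursts) > 0) {
    p <- p + ggplot2::geom_rect(
      data = bursts,
      ggplot2::aes(xmin = .data$start_s, xmax = .data$end_s,
                   ymin = -0.1, ymax = 1.1),
      alpha = 0.25, fill = "orange"
    )
  }
  p
}

#' Plot the surrogate distribution of a permutation test
#'
#' Histogram of the surrogate absolute mean differences with the observed
#' difference marked; the exceedance count is the mass at or right of the
#' line.
#'
#' @param object A `da_perm_test`.
#' @param bins Histogram bins (default 40).
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot da_perm_test
#' @export
autoplot.da_perm_test <- function(object, bins = 40, ...) {
  ggplot2::ggplot(tibble(delta = object$surrogate_deltas),
                  ggplot2::aes(x = .data$delta)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey70", color = "white") +
    ggplot2::geom_vline(xintercept = object$observed_delta,
                        color = "red", linewidth = 0.8) +
    ggplot2::labs(
      x = "surrogate |mean difference|", y = "count",
      title = sprintf("permutation test: p = %.4g (%s)",
                      object$p_estimate, object$stars)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a peri-event z-score matrix
#'
#' Per-event traces (thin lines) with the across-event mean overlaid and
#' the event onset marked at time 0.
#'
#' @param object A `da_peri_event` from [peri_event_matrix()].
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot da_peri_event
#' @export
autoplot.da_peri_event <- function(object, ...) {
  m <- peri_event_mean(object)
  ggplot2::ggplot() +
    ggplot2::geom_line(
      data = object,
      ggplot2::aes(x = .data$time_rel_s, y = .data$zscore,
                   group = .data$event_id),
      alpha = 0.25, linewidth = 0.3
    ) +
    ggplot2::geom_line(
      data = m,
      ggplot2::aes(x = .data$time_rel_s, y = .data$mean_z),
      color = "blue", linewidth = 0.8
    ) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "time from event (s)", y = "z-score of dF/F") +
    ggplot2::theme_minimal()
}

#' Spine head-diameter histogram with the class boundary
#'
#' @param spines A data frame with `head_diameter_nm` (and optionally
#'   `class`).
#' @param boundary_nm Boundary line position (default 350).
#' @param bins Histogram bins (default 50).
#' @return A ggplot object.
#' @export
plot_spine_classes <- function(spines, boundary_nm = 350, bins = 50) {
  if (!"class" %in% names(spines)) spines <- classify_spines(spines)
  ggplot2::ggplot(spines,
                  ggplot2::aes(x = .data$head_diameter_nm,
                               fill = .data$class)) +
    ggplot2::geom_histogram(bins = bins, position = "identity",
                            alpha = 0.6) +
    ggplot2::geom_vline(xintercept = boundary_nm, linetype = "dashed") +
    ggplot2::labs(x = "head diameter (nm)", y = "spines", fill = NULL) +
    ggplot2::theme_minimal()
}
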