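#' Simulate a dual-channel fiber-photometry recording
#'
#' Produces a signal channel (465 nm, sensor-dependent) and a reference
#' channel (405 nm, activity-independent isosbestic) on a uniform time
#' grid. Both channels share a mono-exponential bleaching baseline, a
#' common motion artifact, and independent Gaussian noise; only the signal
#' channel carries transients. Each transient is a difference of
#' exponentials `exp(-t/tau_decay) - exp(-t/tau_rise)` normalized to unit
#' peak, whose analytic peak lag after onset is
#' `log(tau_decay / tau_rise) * tau_rise * tau_decay / (tau_decay - tau_rise)`.
#' The transient term is applied in fractional (dF/F) units — the signal
#' channel is `baseline * (1 + amplitude * kernel)` — so `amplitude` is
#' the true dF/F peak regardless of how far bleaching has progressed.
#'
#' @param duration_s Recording length (s).
#' @param fs_hz Sampling rate (Hz).
#' @param event_times_s Strictly increasing transient onset times within
#'   `[0, duration_s]`.
#' @param amplitude Transient peak in dF/F units (e.g. 0.05 = 5%).
#' @param tau_rise_s,tau_decay_s Kernel time constants; rise < decay.
#' @param f0 Baseline fluorescence level at t = 0 (arbitrary units).
#' @param bleach_tau_s Mono-exponential bleaching time constant.
#' @param noise_sd Per-channel additive Gaussian noise SD (same units as
#'   `f0`).
#' @param motion_sd SD of the shared motion artifact (smoothed Gaussian
#'   process added to both channels).
#' @param seed Integer seed.
#' @return A tibble (`time_s`, `f465`, `f405`) with attributes `fs_hz`,
#'   `event_times_s`, `kernel_peak_lag_s`, and `true_dff` (the noise-free
#'   fractional transient series, for recovery tests).
#' @examples
#' tr <- sim_photometry(duration_s = 30, fs_hz = 20, event_times_s = 10,
#'                      seed = 1)
#' @export
sim_photometry <- function(duration_s, fs_hz = 20, event_times_s = numeric(0),
                           amplitude = 0.05, tau_rise_s = 0.2,
                           tau_decay_s = 1.5, f0 = 100,
                           bleach_tau_s = 600, noise_sd = 0.2,
                           motion_sd = 0, seed) {
  .check_number(duration_s, "duration_s", lower = 0, strict_lower = TRUE)
  .check_number(fs_hz, "fs_hz", lower = 0, strict_lower = TRUE)
  .check_number(tau_rise_s, "tau_rise_s", lower = 0, strict_lower = TRUE)
  .check_number(tau_decay_s, "tau_decay_s", lower = tau_rise_s,
                strict_lower = TRUE)
  .check_number(amplitude, "amplitude")
  .check_number(noise_sd, "noise_sd", lower = 0)
  .check_number(motion_sd, "motion_sd", lower = 0)
  .check_number(bleach_tau_s, "bleach_tau_s", lower = 0, strict_lower = TRUE)
  seed <- .check_seed(seed)
  ev <- as.numeric(event_times_s)
  if (length(ev)) {
    if (anyNA(ev) || is.unsorted(ev, strictly = TRUE)) {
      abort("event times must be strictly increasing with no duplicates.")
    }
    if (min(ev) < 0 || max(ev) > duration_s) {
      abort("event times must lie within [0, duration_s].")
    }
  }

  t <- seq(0, duration_s, by = 1 / fs_hz)
  n <- length(t)
  bleach <- f0 * exp(-t / bleach_tau_s)

  kernel_norm <- {
    tp <- log(tau_decay_s / tau_rise_s) * tau_rise_s * tau_decay_s /
      (tau_decay_s - tau_rise_s)
    exp(-tp / tau_decay_s) - exp(-tp / tau_rise_s)
  }
  frac <- numeric(n)
  for (e in ev) {
    dt <- t - e
    on <- dt >= 0
    frac[on] <- frac[on] +
      (exp(-dt[on] / tau_decay_s) - exp(-dt[on] / tau_rise_s)) / kernel_norm
  }
  true_dff <- amplitude * frac

  withr::with_seed(seed, {
    motion <- if (motion_sd > 0) {
      # smoothed white noise: slow common-mode artifact both channels share
      raw <- rnorm(n)
      w <- max(3L, as.integer(fs_hz / 2))
      sm <- stats::filter(raw, rep(1 / w, w), sides = 2)
      sm[is.na(sm)] <- 0
      motion_sd * as.numeric(sm) / max(sd(sm[sm != 0]), 1e-12)
    } else {
      numeric(n)
    }
    f465 <- bleach * (1 + true_dff) + motion + rnorm(n, 0, noise_sd)
    f405 <- bleach + motion + rnorm(n, 0, noise_sd)
    out <- tibble(time_s = t, f465 = f465, f405 = f405)
    attr(out, "fs_hz") <- fs_hz
    attr(out, "event_times_s") <- ev
    attr(out, "kernel_peak_lag_s") <-
      log(tau_decay_s / tau_rise_s) * tau_rise_s * tau_decay_s /
      (tau_decay_s - tau_rise_s)
    attr(out, "true_dff") <- true_dff
    attr(out, "seed") <- seed
    out
  })
}

#' Simulate a table of dendritic spine head diameters
#'
#' Draws spine head diameters from a two-component Gaussian mixture: a
#' thin component below the 350 nm class boundary and a mushroom component
#' above it. The constructor refuses mixtures whose components put more
#' than `straddle_tol` probability mass on the wrong side of 350 nm, since
#' ground-truth class labels would then be ambiguous.
#'
#' @param n Number of spines (0 allowed: returns an empty table).
#' @param p_mushroom Probability a spine is mushroom, in \[0, 1\].
#' @param thin_mean_nm,thin_sd_nm Thin component (default 250 +/- 40 nm).
#' @param mushroom_mean_nm,mushroom_sd_nm Mushroom component (default
#'   500 +/- 60 nm).
#' @param straddle_tol Maximum tolerated probability mass of a component
#'   on the wrong side of 350 nm (default 0.025).
#' @param seed Integer seed.
#' @param dendrite_id Optional identifier attached to all rows.
#' @return A tibble: `spine_id`, `head_diameter_nm`, `true_class`
#'   (`"thin"`/`"mushroom"`), plus `dendrite_id` if given. Diameters are
#'   truncated at a 1 nm floor.
#' @examples
#' sim_spine_table(5, p_mushroom = 0.4, seed = 1)
#' @export
sim_spine_table <- function(n, p_mushroom = 0.4, thin_mean_nm = 250,
                            thin_sd_nm = 40, mushroom_mean_nm = 500,
                            mushroom_sd_nm = 60, straddle_tol = 0.025,
                            seed, dendrite_id = NULL) {
  .check_number(n, "n", lower = 0)
  .check_number(p_mushroom, "p_mushroom", lower = 0, upper = 1)
  .check_number(thin_sd_nm, "thin_sd_nm", lower = 0, strict_lower = TRUE)
  .check_number(mushroom_sd_nm, "mushroom_sd_nm", lower = 0,
                strict_lower = TRUE)
  leak_thin <- 1 - stats::pnorm(350, thin_mean_nm, thin_sd_nm)
  leak_mush <- stats::pnorm(350, mushroom_mean_nm, mushroom_sd_nm)
  if (leak_thin > straddle_tol || leak_mush > straddle_tol) {
    abort(sprintf(
      "mixture straddles the 350 nm boundary (thin leak %.3f, mushroom leak %.3f > tol %.3f); ground truth would be ambiguous.",
      leak_thin, leak_mush, straddle_tol
    ))
  }
  seed <- .check_seed(seed)
  out <- withr::with_seed(seed, {
    if (n == 0) {
      tibble(spine_id = character(), head_diameter_nm = numeric(),
             true_class = character())
    } else {
      is_m <- runif(n) < p_mushroom
      d <- ifelse(is_m,
                  rnorm(n, mushroom_mean_nm, mushroom_sd_nm),
                  rnorm(n, thin_mean_nm, thin_sd_nm))
      tibble(
        spine_id = paste0("s", seq_len(n)),
        head_diameter_nm = pmax(d, 1),
        true_class = ifelse(is_m, "mushroom", "thin")
      )
    }
  })
  if (!is.null(dendrite_id)) out <- tibble(dendrite_id = dendrite_id, out)
  attr(out, "seed") <- seed
  out
}
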