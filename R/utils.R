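# internal validation / seed helpers

.check_number <- function(x, name, lower = -Inf, upper = Inf,
                          strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  lo_ok <- if (strict_lower) x > lower else x >= lower
  hi_ok <- if (strict_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok) {
    abort(sprintf(
      "`%s` must be in %s%s, %s%s (got %g).", name,
      if (strict_lower) "(" else "[", format(lower),
      format(upper), if (strict_upper) ")" else "]", x
    ))
  }
  invisible(x)
}

.check_seed <- function(seed) {
  if (is.null(seed)) abort("`seed` must be supplied (an integer).")
  .check_number(seed, "seed")
  if (seed != round(seed)) abort("`seed` must be an integer.")
  as.integer(seed %% .Machine$integer.max)
}

#' Derive a deterministic per-stage seed
#'
#' Maps one master seed to distinct, reproducible stage seeds so that
#' pipeline stages never share RNG streams. The result is always a valid
#' 32-bit integer seed.
#'
#' @param seed Master integer seed.
#' @param stage One of `"simulate"`, `"ephys"`, `"photometry"`,
#'   `"morpho"`, `"stats"`.
#' @return An integer seed below 2^31.
#' @export
derive_seed <- function(seed, stage) {
  seed <- .check_seed(seed)
  offs <- c(simulate = 101L, ephys = 211L, photometry = 307L,
            morpho = 401L, stats = 503L)
  k <- offs[[stage]] %||% abort(sprintf("unknown stage '%s'", stage))
  as.integer((as.numeric(seed) * 48271 + k) %% 2147483647)
}

# spike times compared in integer microseconds to avoid float-boundary
# ambiguity at the 80/160 ms thresholds
.times_to_us <- function(t_s) as.integer(round(t_s * 1e6))

.spike_vector <- function(spikes) {
  if (is.data.frame(spikes)) {
    if (!"spike_time_s" %in% names(spikes)) {
      abort("data-frame input needs a `spike_time_s` column.")
    }
    spikes <- spikes$spike_time_s
  }
  if (!is.numeric(spikes)) abort("spike times must be numeric.")
  if (anyNA(spikes) || any(!is.finite(spikes))) {
    abort("spike times must be finite and non-missing.")
  }
  if (is.unsorted(spikes, strictly = TRUE)) {
    abort("spike times must be strictly increasing.")
  }
  as.numeric(spikes)
}
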