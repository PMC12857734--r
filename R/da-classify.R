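#' Putative dopamine-neuron inclusion gate
#'
#' Applies the four in-vivo electrophysiological criteria used to accept a
#' recorded unit as a putative dopamine (DA) neuron: (i) a triphasic action
#' potential with a marked negative deflection, (ii) total spike duration
#' > 2.0 ms, (iii) start-to-negative-trough width > 1.1 ms, and (iv) a slow
#' firing rate strictly between 1 and 10 Hz. A unit is included only when
#' all four hold; otherwise every violated criterion is reported.
#'
#' @param features A data frame with columns `triphasic` (logical),
#'   `duration_ms`, `start_to_trough_ms`, `mean_rate_hz`, and optionally
#'   `neuron_id`.
#' @return The input as a tibble with two added columns: `included`
#'   (logical) and `reasons` (comma-separated violated criteria among
#'   `"triphasic"`, `"duration"`, `"width"`, `"rate"`; `""` when included).
#' @examples
#' classify_da_neurons(data.frame(
#'   neuron_id = c("a", "b"),
#'   triphasic = c(TRUE, TRUE),
#'   duration_ms = c(2.5, 2.5),
#'   start_to_trough_ms = c(1.3, 1.3),
#'   mean_rate_hz = c(4.2, 12)
#' ))
#' @export
classify_da_neurons <- function(features) {
  if (!is.data.frame(features)) abort("`features` must be a data frame.")
  need <- c("triphasic", "duration_ms", "start_to_trough_ms", "mean_rate_hz")
  miss <- setdiff(need, names(features))
  if (length(miss)) {
    abort(paste0("missing feature columns: ", paste(miss, collapse = ", ")))
  }
  num <- c("duration_ms", "start_to_trough_ms", "mean_rate_hz")
  for (col in num) {
    v <- features[[col]]
    if (!is.numeric(v) || anyNA(v) || any(v < 0)) {
      abort(sprintf("`%s` must be non-negative and non-missing.", col))
    }
  }
  features <- as_tibble(features)
  reasons <- purrr::pmap_chr(
    features[c("triphasic", num)],
    function(triphasic, duration_ms, start_to_trough_ms, mean_rate_hz) {
      bad <- c(
        if (!isTRUE(triphasic)) "triphasic",
        if (!(duration_ms > 2.0)) "duration",
        if (!(start_to_trough_ms > 1.1)) "width",
        if (!(mean_rate_hz > 1 && mean_rate_hz < 10)) "rate"
      )
      paste(bad, collapse = ",")
    }
  )
  features$included <- reasons == ""
  features$reasons <- reasons
  features
}
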