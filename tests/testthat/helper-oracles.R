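# Independent oracles, written deliberately in a different style from the
# package internals so they can disagree.

# Naive two-threshold burst scanner: explicit state machine over ISIs in
# integer milliseconds. Returns a matrix with columns first, last (spike
# indices), or NULL when no burst exists.
naive_burst_scan <- function(t_s, onset_ms = 80, cont_ms = 160) {
  t_ms <- round(t_s * 1000)
  n <- length(t_ms)
  res <- list()
  cur <- NULL
  i <- 1L
  while (i <= n - 1L) {
    gap <- t_ms[i + 1L] - t_ms[i]
    if (is.null(cur)) {
      if (gap < onset_ms) cur <- c(i, i + 1L)
    } else {
      if (gap <= cont_ms) {
        cur[2L] <- i + 1L
      } else {
        res[[length(res) + 1L]] <- cur
        cur <- NULL
      }
    }
    i <- i + 1L
  }
  if (!is.null(cur)) res[[length(res) + 1L]] <- cur
  if (length(res) == 0L) return(NULL)
  do.call(rbind, res)
}

# Random spike train on a 1-ms grid whose ISI mixture deliberately hits
# the 79/80/81 and 159/160/161 ms boundaries.
random_train_ms <- function(n_spikes) {
  pick <- sample.int(4L, n_spikes - 1L, replace = TRUE)
  isi_ms <- vapply(pick, function(p) {
    switch(p,
      max(1, round(rexp(1, 1 / 50))),        # short, intra-burst-like
      round(runif(1, 60, 180)),              # straddles both thresholds
      round(rexp(1, 1 / 400)) + 161,         # long, inter-burst
      sample(c(79, 80, 81, 159, 160, 161), 1) # exact boundaries
    )
  }, numeric(1))
  cumsum(c(0, isi_ms)) / 1000
}

expected_swb <- function(p, k) 100 * p * k / (p * k + 1 - p)
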