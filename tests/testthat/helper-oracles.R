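# Shared fixtures and independent oracles used across test files.

# exhaustive maximum one-to-one matching within tolerance (exponential
# search; independent of the package's DP matcher, usable up to ~8 events)
brute_force_matches <- function(detected, reference, tol) {
  rec <- function(di, used) {
    if (di > length(detected)) return(0L)
    best <- rec(di + 1L, used)  # leave this detection unmatched
    for (j in seq_along(reference)) {
      if (!used[j] && abs(detected[di] - reference[j]) <= tol) {
        used[j] <- TRUE
        best <- max(best, 1L + rec(di + 1L, used))
        used[j] <- FALSE
      }
    }
    best
  }
  rec(1L, rep(FALSE, length(reference)))
}

# rising-edge detector written independently of impulse_detect
naive_rising_edges <- function(x, threshold) {
  out <- integer()
  prev <- 0L
  for (i in seq_along(x)) {
    cur <- as.integer(x[i] > threshold)
    if (cur == 1L && prev == 0L) out <- c(out, i)
    prev <- cur
  }
  out
}

# a clean asymmetric pulse train for PPG tests: maxima exactly at `peaks`
make_pulse_train <- function(peaks, fs = 2000, dur = NULL) {
  if (is.null(dur)) dur <- max(peaks) + 0.6
  t <- seq(0, dur, by = 1 / fs)
  x <- numeric(length(t))
  shape <- 2.5; scale <- 0.08; ms <- (shape - 1) * scale
  for (p in peaks) {
    u <- (t - p + ms) / scale
    v <- ifelse(u > 0, u^(shape - 1) * exp(-(u - (shape - 1))), 0)
    x <- x + v / ((shape - 1)^(shape - 1))
  }
  waveform(x, fs, "PPG")
}

# spectral amplitude of a single tone estimated from the middle of the
# record (avoids edge transients)
tone_amplitude <- function(x, fs, freq) {
  n <- length(x)
  mid <- x[round(n / 4):round(3 * n / 4)]
  sqrt(2) * sqrt(mean((mid - mean(mid))^2))
}
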