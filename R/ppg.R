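# PPG branch: systolic-peak detection.

#' Detect PPG systolic peaks
#'
#' Finds the per-beat maxima of the pulse waveform. The signal is first
#' smoothed with a zero-phase 0.5-8 Hz band-pass (the beat-frequency band),
#' then strict local maxima are selected greedily by height under a
#' physiological refractory period of `60 / max_hr_bpm` seconds. Dicrotic
#' and diastolic humps are rejected by a prominence floor of 0.3 times the
#' median candidate prominence. Each retained peak is refined to the raw
#' waveform maximum within +-25 ms.
#'
#' A flat (or effectively constant) signal yields an empty peak list, not
#' an error.
#'
#' @param ppg a [waveform()] (PPG channel).
#' @param min_hr_bpm,max_hr_bpm plausible heart-rate range; `max_hr_bpm`
#'   sets the refractory period.
#' @param smooth_band_hz two-element band for the internal smoothing
#'   filter, in Hz.
#' @return An object of class `systolic_peaks` with fields `times`
#'   (strictly increasing seconds) and `prominences`.
#' @export
detect_systolic_peaks <- function(ppg, min_hr_bpm = 40, max_hr_bpm = 180,
                                  smooth_band_hz = c(0.5, 8)) {
  stopifnot(inherits(ppg, "waveform"))
  x <- ppg$samples
  empty <- structure(list(times = numeric(), prominences = numeric()),
                     class = "systolic_peaks")
  if (length(x) < 8L || stats::sd(x) < .Machine$double.eps^0.5 * max(abs(x), 1))
    return(empty)
  spec <- bandpass_spec(smooth_band_hz[1], smooth_band_hz[2], order = 2)
  sm <- .bandpass_num(x - mean(x), ppg$fs, spec)
  # strict interior local maxima of the smoothed trace
  d <- diff(sm)
  cand <- which(d[-length(d)] > 0 & d[-1L] <= 0) + 1L
  if (!length(cand)) return(empty)
  refractory <- round(60 / max_hr_bpm * ppg$fs)
  cand <- cand[order(sm[cand], decreasing = TRUE)]
  kept <- integer()
  for (i in cand) {
    if (!length(kept) || all(abs(kept - i) >= refractory)) kept <- c(kept, i)
  }
  kept <- sort(kept)
  prom <- .peak_prominence(sm, kept)
  floor_ <- 0.3 * stats::median(prom)
  sel <- prom >= floor_
  kept <- kept[sel]
  prom <- prom[sel]
  if (!length(kept)) return(empty)
  # refine to the raw-signal maximum within +-25 ms
  halfw <- round(0.025 * ppg$fs)
  refined <- vapply(kept, function(i) {
    a <- max(1L, i - halfw)
    b <- min(length(x), i + halfw)
    as.integer(a - 1L + which.max(x[a:b]))
  }, integer(1))
  o <- order(refined)
  refined <- refined[o]
  prom <- prom[o]
  dup <- c(TRUE, diff(refined) > 0)
  structure(list(times = ppg$t0 + (refined[dup] - 1) / ppg$fs,
                 prominences = prom[dup]),
            class = "systolic_peaks")
}

# topographic prominence of peaks at indices `idx` in signal `x`:
# height above the higher of the two valley floors separating the peak
# from higher ground (or from the signal edge).
.peak_prominence <- function(x, idx) {
  vapply(idx, function(i) {
    h <- x[i]
    left <- if (i > 1L) x[seq_len(i - 1L)] else numeric()
    right <- if (i < length(x)) x[(i + 1L):length(x)] else numeric()
    valley <- function(side, rev = FALSE) {
      if (!length(side)) return(min(x))
      if (rev) side <- rev(side)
      higher <- which(side > h)      # side is ordered moving away from peak
      if (length(higher)) min(side[seq_len(higher[1L])]) else min(side)
    }
    lo_l <- valley(left, rev = TRUE)
    lo_r <- valley(right)
    h - max(lo_l, lo_r)
  }, numeric(1))
}
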