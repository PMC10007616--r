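# Band-pass noise reduction and windowed segmentation.

#' Band-pass filter specification
#'
#' Heart sounds carry most of their energy between roughly 20 and 200 Hz;
#' the default preprocessing band removes baseline wander and rumble below
#' 20 Hz and broadband hiss above 200 Hz.
#'
#' @param low_hz,high_hz corner frequencies in Hz, `0 < low < high`.
#' @param order Butterworth order of the one-pass prototype (the filter is
#'   applied forward-backward, so the effective attenuation is doubled and
#'   the phase response is zero).
#' @return An object of class `bandpass_spec`.
#' @export
bandpass_spec <- function(low_hz = 20, high_hz = 200, order = 4) {
  if (!(low_hz > 0 && high_hz > low_hz))
    stop("need 0 < low_hz < high_hz")
  if (order < 1) stop("order must be a positive integer")
  structure(list(low_hz = low_hz, high_hz = high_hz, order = order),
            class = "bandpass_spec")
}

# zero-phase Butterworth band-pass on a plain numeric vector
.bandpass_num <- function(x, fs, spec) {
  if (spec$high_hz >= fs / 2)
    stop("high_hz (", spec$high_hz, ") must be below Nyquist (", fs / 2, ")")
  bt <- signal::butter(spec$order, c(spec$low_hz, spec$high_hz) / (fs / 2),
                       type = "pass")
  as.numeric(signal::filtfilt(bt, x))
}

# zero-phase Butterworth low-pass
.lowpass_num <- function(x, fs, high_hz, order = 4) {
  if (high_hz >= fs / 2)
    stop("low-pass cutoff must be below Nyquist")
  bt <- signal::butter(order, high_hz / (fs / 2), type = "low")
  as.numeric(signal::filtfilt(bt, x))
}

#' Zero-phase band-pass filtering
#'
#' Applies the Butterworth band-pass forward and backward
#' (`signal::filtfilt`), so event timing is not shifted and the output has
#' the same length as the input.
#'
#' @param w a [waveform()].
#' @param spec a [bandpass_spec()]; `high_hz` must be below `w$fs / 2`.
#' @return A filtered [waveform()].
#' @export
bandpass <- function(w, spec = bandpass_spec()) {
  stopifnot(inherits(w, "waveform"), inherits(spec, "bandpass_spec"))
  waveform(.bandpass_num(w$samples, w$fs, spec), w$fs, w$channel, w$t0)
}

#' Segmentation plan
#'
#' @param window_s window length in seconds (> 0).
#' @param overlap_s overlap between consecutive windows in seconds,
#'   `0 <= overlap_s < window_s`.
#' @return An object of class `segment_plan`.
#' @export
segment_plan <- function(window_s = 10, overlap_s = 0) {
  if (window_s <= 0) stop("window_s must be positive")
  if (overlap_s < 0 || overlap_s >= window_s)
    stop("need 0 <= overlap_s < window_s")
  structure(list(window_s = window_s, overlap_s = overlap_s),
            class = "segment_plan")
}

#' Split a waveform into windows
#'
#' Windows tile the recording; each segment carries its own `t0` so events
#' detected within it map back to absolute time. With zero overlap the
#' concatenation of segment samples reproduces the input exactly. A final
#' shorter tail segment is kept (a recording shorter than one window yields
#' a single short segment).
#'
#' @param w a [waveform()].
#' @param plan a [segment_plan()].
#' @return List of [waveform()] segments.
#' @export
segment_waveform <- function(w, plan = segment_plan()) {
  stopifnot(inherits(w, "waveform"), inherits(plan, "segment_plan"))
  n <- length(w$samples)
  win <- round(plan$window_s * w$fs)
  step <- win - round(plan$overlap_s * w$fs)
  out <- list()
  s <- 1L
  repeat {
    e <- min(n, s + win - 1L)
    out[[length(out) + 1L]] <- waveform(w$samples[s:e], w$fs, w$channel,
                                        t0 = w$t0 + (s - 1L) / w$fs)
    if (e >= n) break
    s <- s + step
  }
  out
}
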