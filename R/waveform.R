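# Core containers: waveform, recording, annotation_set.

#' Uniformly sampled waveform
#'
#' A waveform is the basic container for a single channel of a cardiac
#' recording: a numeric vector of amplitudes, its sampling rate, a channel
#' label and a start-time offset. Sample index `i` (1-based) corresponds to
#' time `t0 + (i - 1) / fs` seconds, so event times are always seconds from
#' recording start.
#'
#' @param samples numeric vector of amplitudes (volts or normalised a.u.).
#' @param fs sampling rate in Hz; must be positive.
#' @param channel channel label, one of `"PCG"`, `"PPG"`, `"ECG"`, `"OTHER"`.
#' @param t0 start-time offset in seconds (used by windowed segments so that
#'   locally detected events map back to absolute time).
#' @return An object of class `waveform`.
#' @examples
#' w <- waveform(sin(2 * pi * 50 * seq(0, 1, by = 1/2000)), fs = 2000)
#' duration(w)
#' @export
waveform <- function(samples, fs, channel = c("PCG", "PPG", "ECG", "OTHER"),
                     t0 = 0) {
  channel <- match.arg(channel)
  samples <- as.numeric(samples)
  if (length(samples) < 1L) stop("waveform needs at least one sample")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("fs must be a single positive number")
  structure(list(samples = samples, fs = fs, channel = channel, t0 = t0),
            class = "waveform")
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf("<waveform> %s: %d samples @ %g Hz (%.3f s), t0 = %g s\n",
              x$channel, length(x$samples), x$fs, duration(x), x$t0))
  invisible(x)
}

#' Duration of a waveform in seconds
#' @param w a [waveform()].
#' @return length(samples) / fs, in seconds.
#' @export
duration <- function(w) length(w$samples) / w$fs

#' Synchronised two-channel recording
#'
#' Couples a chest phonocardiogram (PCG) and a finger photoplethysmogram
#' (PPG) acquired on one clock. Both channels must share the sampling rate
#' and cover the same time span to within one sample period.
#'
#' @param pcg,ppg [waveform()] objects for the acoustic and optical channel.
#' @param subject_id optional subject identifier.
#' @param metadata named list of free-form strings.
#' @return An object of class `recording`.
#' @export
recording <- function(pcg, ppg, subject_id = "", metadata = list()) {
  stopifnot(inherits(pcg, "waveform"), inherits(ppg, "waveform"))
  if (pcg$fs != ppg$fs)
    stop("fs mismatch: PCG at ", pcg$fs, " Hz, PPG at ", ppg$fs, " Hz")
  if (abs(duration(pcg) - duration(ppg)) > 1 / pcg$fs)
    stop("channels must cover the same time span within one sample period")
  structure(list(pcg = pcg, ppg = ppg, subject_id = subject_id,
                 metadata = metadata),
            class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> subject '%s': %.1f s @ %g Hz (PCG + PPG)\n",
              x$subject_id, duration(x$pcg), x$pcg$fs))
  invisible(x)
}

#' Reference event annotations
#'
#' Ground-truth event times for a recording: first heart sound (S1) onsets,
#' second heart sound (S2) onsets, and PPG systolic-peak times, all in
#' seconds from recording start. Each list must be strictly increasing;
#' unsorted input is sorted with a warning.
#'
#' @param s1_times,s2_times,systolic_peak_times numeric vectors of seconds.
#' @return An object of class `annotation_set`.
#' @export
annotation_set <- function(s1_times = numeric(), s2_times = numeric(),
                           systolic_peak_times = numeric()) {
  fix <- function(x, what) {
    x <- as.numeric(x)
    if (is.unsorted(x, strictly = TRUE) && length(x) > 1L) {
      warning(what, " times not strictly increasing; sorting")
      x <- sort(unique(x))
    }
    x
  }
  structure(list(s1_times = fix(s1_times, "S1"),
                 s2_times = fix(s2_times, "S2"),
                 systolic_peak_times = fix(systolic_peak_times, "systolic peak")),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("<annotation_set> %d S1, %d S2, %d systolic peaks\n",
              length(x$s1_times), length(x$s2_times),
              length(x$systolic_peak_times)))
  invisible(x)
}
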