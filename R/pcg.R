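# The PCG branch: analytic signal, envelope filtering, Shannon entropy,
# smoothing, normalisation, impulse conversion and start-point extraction.

#' Analytic-signal envelope and phase
#'
#' Builds the analytic signal by zeroing the negative-frequency half of the
#' spectrum (doubling the positive half), so its modulus is the
#' instantaneous envelope `m(t)` and `samples / m(t)` recovers the cosine
#' of the instantaneous phase. For a pure tone `cos(wt)` the imaginary part
#' is the quadrature `sin(wt)` and the envelope is identically 1. The
#' envelope dominates the signal: `m(t) >= |s(t)|` everywhere (up to FFT
#' round-off).
#'
#' @param w a [waveform()] with at least two samples.
#' @return An object of class `analytic_envelope` with fields `envelope`
#'   (nonnegative), `phase_cos` (in \[-1, 1\]; 0 where the envelope
#'   vanishes) and `fs`.
#' @export
analytic_transform <- function(w) {
  stopifnot(inherits(w, "waveform"))
  x <- w$samples
  n <- length(x)
  if (n < 2L) stop("analytic_transform needs at least 2 samples")
  X <- stats::fft(x)
  h <- numeric(n)
  h[1L] <- 1
  if (n %% 2L == 0L) {
    h[n / 2 + 1L] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[2:((n + 1) / 2)] <- 2
  }
  sa <- stats::fft(X * h, inverse = TRUE) / n
  env <- Mod(sa)
  eps <- .Machine$double.eps^0.5 * max(env)
  phc <- ifelse(env > eps, x / env, 0)
  phc <- pmin(pmax(phc, -1), 1)
  structure(list(envelope = env, phase_cos = phc, fs = w$fs, t0 = w$t0),
            class = "analytic_envelope")
}

#' Envelope filtering: raise S2 bursts to the S1 amplitude level
#'
#' The second heart sound is systematically weaker than the first, so a
#' single global detection threshold tends to treat S2 as noise. Envelope
#' filtering (EF) removes that amplitude handicap: the envelope is filtered
#' with a zero-phase filter, a threshold `delta * mean(mfilt)` separates
#' burst regions from the baseline, and every contiguous supra-threshold
#' region is rescaled so that its peak reaches the global envelope maximum
#' (the S1 amplitude level). Multiplying the boosted envelope by the
#' instantaneous-phase cosine reconstructs an amplitude-equalised waveform
#' `z(t)`.
#'
#' The default envelope filter is a 40 Hz zero-phase low-pass: the envelope
#' of 20-200 Hz heart-sound bursts varies on a scale of tens of
#' milliseconds (content below ~30 Hz), and the threshold rule relies on
#' the envelope's baseline level, which a band-pass with a nonzero low
#' corner would remove. A [bandpass_spec()] may be supplied instead.
#'
#' @param ae an [analytic_transform()] result.
#' @param delta nonnegative threshold multiplier applied to the mean of the
#'   filtered envelope; `delta = 0` boosts every positive region.
#' @param band either a single low-pass cutoff in Hz (default 40) or a
#'   [bandpass_spec()] applied to the envelope.
#' @return An object of class `filtered_envelope` with fields `mfilt` (the
#'   filtered envelope), `boosted`, `z` (`boosted * phase_cos`),
#'   `threshold_value` and `delta`.
#' @export
envelope_filter <- function(ae, delta = 2, band = 40) {
  stopifnot(inherits(ae, "analytic_envelope"))
  if (delta < 0) stop("delta must be nonnegative")
  mfilt <- if (inherits(band, "bandpass_spec")) {
    .bandpass_num(ae$envelope, ae$fs, band)
  } else {
    .lowpass_num(ae$envelope, ae$fs, band)
  }
  thr <- delta * mean(mfilt)
  boosted <- mfilt
  above <- mfilt > thr
  if (any(above)) {
    a_ref <- max(mfilt)
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (i in seq_along(r$values)) {
      if (!r$values[i]) next
      idx <- starts[i]:ends[i]
      pk <- max(mfilt[idx])
      if (pk > 0) boosted[idx] <- mfilt[idx] * (a_ref / pk)
    }
  }
  structure(list(mfilt = mfilt, boosted = boosted,
                 z = boosted * ae$phase_cos,
                 threshold_value = thr, delta = delta, fs = ae$fs),
            class = "filtered_envelope")
}

#' Shannon entropy kernel
#'
#' Rescales the magnitude of the input to \[0, 1\] by min-max and applies
#' the entropy kernel `-x * ln(x)` sample-wise, with the convention
#' `0 * ln(0) = 0`. The kernel is bounded by `1/e` (attained at `x = 1/e`)
#' and de-emphasises the extremes of the normalised scale in favour of
#' mid-level intensities. Constant input maps to all zeros.
#'
#' In the detection pipeline the kernel is applied to the normalised
#' instantaneous *energy* (the squared working signal), which suppresses
#' the noise floor quadratically before the kernel weighting; see
#' [run_model()].
#'
#' @param x numeric vector.
#' @return Numeric vector of the same length, values in \[0, 1/e\].
#' @export
shannon_entropy <- function(x) {
  xa <- abs(x)
  rng <- range(xa)
  if (rng[2] - rng[1] <= .Machine$double.eps * max(rng[2], 1))
    return(numeric(length(x)))
  xh <- (xa - rng[1]) / (rng[2] - rng[1])
  ifelse(xh > 0, -xh * log(xh), 0)
}

#' Savitzky-Golay smoothing of the entropy trace
#'
#' Local least-squares polynomial smoothing, which preserves peak position
#' and height better than a moving average. The window length in samples
#' is `round(window_s * fs)` forced odd (the classical 900-sample window at
#' 2000 Hz becomes 901). Polynomials up to `polyorder` pass through
#' unchanged.
#'
#' @param se numeric vector (entropy trace).
#' @param fs sampling rate in Hz.
#' @param window_s window length in seconds.
#' @param polyorder polynomial degree; must be smaller than the window
#'   length in samples.
#' @return Smoothed numeric vector, same length as `se`.
#' @export
smooth_entropy <- function(se, fs, window_s = 0.45, polyorder = 3) {
  n <- round(window_s * fs)
  if (n %% 2L == 0L) n <- n + 1L
  if (n <= polyorder)
    stop("smoothing window (", n, " samples) must exceed polyorder (",
         polyorder, ")")
  as.numeric(signal::sgolayfilt(se, p = polyorder, n = n))
}

#' Min-max normalisation to \[0, 1\]
#'
#' `(x - min) / (max - min)`; a constant vector maps to all zeros.
#'
#' @param x numeric vector.
#' @return Numeric vector in \[0, 1\].
#' @export
normalize_minmax <- function(x) {
  rng <- range(x)
  if (rng[2] - rng[1] <= .Machine$double.eps * max(abs(rng), 1))
    return(numeric(length(x)))
  (x - rng[1]) / (rng[2] - rng[1])
}

#' Threshold the normalised entropy into an impulse train
#'
#' A sample is active when the normalised entropy exceeds `sigma` times its
#' mean; the rising edges (0 to 1 transitions, including an active first
#' sample) are the candidate event start points.
#'
#' @param nse numeric vector in \[0, 1\] (normalised smoothed entropy).
#' @param sigma nonnegative threshold multiplier (default 5).
#' @param fs sampling rate in Hz, stored for start-point conversion.
#' @return An object of class `impulse_train` with fields `impulse` (0/1
#'   integer vector), `start_indices` (1-based rising-edge indices), `fs`
#'   and `sigma`.
#' @export
impulse_detect <- function(nse, sigma = 5, fs = 1) {
  if (sigma < 0) stop("sigma must be nonnegative")
  imp <- as.integer(nse > sigma * mean(nse))
  starts <- which(diff(c(0L, imp)) == 1L)
  structure(list(impulse = imp, start_indices = starts, fs = fs,
                 sigma = sigma),
            class = "impulse_train")
}

#' Convert impulse rising edges to heart-sound candidate times
#'
#' Start indices become times `(index - 1) / fs + t0`. Optionally, start
#' points closer than `min_gap_s` to the previously kept one are merged
#' (keeping the first), which suppresses chattering at threshold crossings;
#' S1 and S2 are at least ~200 ms apart at rest, so the pipeline uses a
#' 100 ms gap.
#'
#' @param it an [impulse_detect()] result.
#' @param t0 segment start offset in seconds.
#' @param min_gap_s minimum spacing between kept start points (default 0,
#'   i.e. keep all rising edges).
#' @return An object of class `heart_sound_candidates` with field `times`
#'   (strictly increasing seconds).
#' @export
extract_startpoints <- function(it, t0 = 0, min_gap_s = 0) {
  stopifnot(inherits(it, "impulse_train"))
  times <- (it$start_indices - 1) / it$fs + t0
  times <- .merge_close(times, min_gap_s)
  structure(list(times = times), class = "heart_sound_candidates")
}

# keep the first of any run of events closer than gap to the last kept one
.merge_close <- function(times, gap) {
  if (gap <= 0 || length(times) < 2L) return(times)
  keep <- times[1L]
  for (t in times[-1L]) if (t - keep[length(keep)] >= gap) keep <- c(keep, t)
  keep
}

#' Combine heart-sound candidate sets
#'
#' Merges per-segment candidate lists by absolute time, removing duplicate
#' events closer than `dedup_s` (as arise from overlapping windows).
#'
#' @param cand_list list of `heart_sound_candidates`.
#' @param dedup_s events closer than this are considered duplicates
#'   (default 50 ms).
#' @param amplitudes optional list of per-candidate amplitudes, merged in
#'   parallel.
#' @return A `heart_sound_candidates` object.
#' @export
merge_candidates <- function(cand_list, dedup_s = 0.05, amplitudes = NULL) {
  times <- unlist(lapply(cand_list, function(c) c$times))
  amps <- if (is.null(amplitudes)) NULL else unlist(amplitudes)
  o <- order(times)
  times <- times[o]
  if (!is.null(amps)) amps <- amps[o]
  if (length(times) > 1L) {
    keep <- c(TRUE, diff(times) >= dedup_s)
    times <- times[keep]
    if (!is.null(amps)) amps <- amps[keep]
  }
  out <- structure(list(times = times), class = "heart_sound_candidates")
  if (!is.null(amps)) out$amplitudes <- amps
  out
}
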