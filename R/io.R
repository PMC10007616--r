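# Reading and writing waveforms (WAV, CSV) and annotation files.
#
# WAV support is a minimal RIFF implementation (PCM16 and IEEE float32,
# mono or interleaved multichannel) built on readBin/writeBin.

#' Read a RIFF/WAV file
#'
#' Supports 16-bit PCM and 32-bit IEEE float encodings, mono or
#' multichannel. PCM samples are scaled to \[-1, 1\].
#'
#' @param path file path.
#' @return list with `data` (numeric matrix, one column per channel) and
#'   `fs` (sampling rate in Hz).
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  readBin(con, "integer", 1, size = 4, endian = "little")
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)
  fmt <- NULL; data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    sz <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      buf <- readBin(con, "raw", sz)
      fmt <- list(
        audio_format = readBin(buf[1:2], "integer", 1, size = 2,
                               endian = "little", signed = FALSE),
        channels = readBin(buf[3:4], "integer", 1, size = 2,
                           endian = "little", signed = FALSE),
        fs = readBin(buf[5:8], "integer", 1, size = 4, endian = "little"),
        bits = readBin(buf[15:16], "integer", 1, size = 2,
                       endian = "little", signed = FALSE))
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", sz)
    } else {
      readBin(con, "raw", sz + sz %% 2L)  # skip unknown chunk (word aligned)
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) stop("incomplete WAV file: ", path)
  if (fmt$audio_format == 1L && fmt$bits == 16L) {
    x <- readBin(data_raw, "integer", length(data_raw) / 2, size = 2,
                 endian = "little") / 32767
  } else if (fmt$audio_format == 3L && fmt$bits == 32L) {
    x <- readBin(data_raw, "numeric", length(data_raw) / 4, size = 4,
                 endian = "little")
  } else {
    stop("unsupported WAV encoding (format ", fmt$audio_format, ", ",
         fmt$bits, " bit)")
  }
  list(data = matrix(x, ncol = fmt$channels, byrow = TRUE), fs = fmt$fs)
}

#' Write a RIFF/WAV file
#'
#' @param data numeric vector (mono) or matrix with one column per channel.
#' @param fs sampling rate in Hz.
#' @param path output file path.
#' @param encoding `"float32"` (bit-exact round trip at single precision)
#'   or `"pcm16"`.
#' @return `path`, invisibly.
#' @export
write_wav <- function(data, fs, path, encoding = c("float32", "pcm16")) {
  encoding <- match.arg(encoding)
  if (is.null(dim(data))) data <- matrix(data, ncol = 1)
  nch <- ncol(data)
  interleaved <- as.numeric(t(data))
  bytes_per <- if (encoding == "pcm16") 2L else 4L
  data_sz <- length(interleaved) * bytes_per
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_sz), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(if (encoding == "pcm16") 1L else 3L, con, size = 2,
           endian = "little")
  writeBin(as.integer(nch), con, size = 2, endian = "little")
  writeBin(as.integer(fs), con, size = 4, endian = "little")
  writeBin(as.integer(fs * nch * bytes_per), con, size = 4, endian = "little")
  writeBin(as.integer(nch * bytes_per), con, size = 2, endian = "little")
  writeBin(8L * bytes_per, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_sz), con, size = 4, endian = "little")
  if (encoding == "pcm16") {
    writeBin(as.integer(round(pmax(pmin(interleaved, 1), -1) * 32767)), con,
             size = 2, endian = "little")
  } else {
    writeBin(interleaved, con, size = 4, endian = "little")
  }
  invisible(path)
}

#' Read a synchronised PCG/PPG recording
#'
#' Accepts either a pair of single-channel WAV files, one multichannel WAV
#' (with `ppg_path = NULL`; channel order declared by `channel_order`), or a
#' CSV file with columns `time,pcg,ppg`. The CSV time column must be a
#' uniform grid (tolerance 1e-6 s). Channels must arrive at a common
#' sampling rate unless `resample_to` is given, in which case both channels
#' are resampled to that rate.
#'
#' @param pcg_path path to the PCG WAV file, the multichannel WAV, or the
#'   CSV file.
#' @param ppg_path path to the PPG WAV file, or `NULL`.
#' @param fmt `"wav"` or `"csv"`.
#' @param resample_to optional target sampling rate in Hz.
#' @param channel_order order of channels in a multichannel WAV.
#' @param subject_id optional subject identifier.
#' @return A [recording()].
#' @export
read_recording <- function(pcg_path, ppg_path = NULL, fmt = c("wav", "csv"),
                           resample_to = NULL,
                           channel_order = c("pcg", "ppg"),
                           subject_id = "") {
  fmt <- match.arg(fmt)
  if (fmt == "csv") {
    d <- utils::read.csv(pcg_path)
    need <- c("pcg", "ppg")
    if (!all(need %in% names(d)))
      stop("CSV must have columns pcg and ppg (and optionally time)")
    if ("time" %in% names(d)) {
      dt <- diff(d$time)
      if (length(dt) && (max(dt) - min(dt)) > 1e-6)
        stop("CSV time column is not a uniform grid")
      fs <- (nrow(d) - 1) / (d$time[nrow(d)] - d$time[1])
    } else {
      stop("CSV without a time column needs one; cannot infer sampling rate")
    }
    pcg <- waveform(d$pcg, fs, "PCG")
    ppg <- waveform(d$ppg, fs, "PPG")
  } else {
    w1 <- read_wav(pcg_path)
    if (is.null(ppg_path)) {
      if (ncol(w1$data) < 2L)
        stop("single WAV given but it has fewer than 2 channels")
      channel_order <- match.arg(channel_order, several.ok = FALSE)
      ip <- if (identical(channel_order, "pcg")) c(1L, 2L) else c(2L, 1L)
      pcg <- waveform(w1$data[, ip[1]], w1$fs, "PCG")
      ppg <- waveform(w1$data[, ip[2]], w1$fs, "PPG")
    } else {
      w2 <- read_wav(ppg_path)
      if (w1$fs != w2$fs && is.null(resample_to))
        stop("fs mismatch: ", w1$fs, " vs ", w2$fs,
             " Hz (pass resample_to= to reconcile)")
      pcg <- waveform(w1$data[, 1], w1$fs, "PCG")
      ppg <- waveform(w2$data[, 1], w2$fs, "PPG")
    }
  }
  if (!is.null(resample_to)) {
    pcg <- resample_waveform(pcg, resample_to)
    ppg <- resample_waveform(ppg, resample_to)
  }
  recording(pcg, ppg, subject_id = subject_id)
}

#' Resample a waveform by Fourier interpolation
#'
#' Changes the sampling rate by truncating or zero-padding the discrete
#' spectrum, which preserves band-limited content exactly: a tone below the
#' output Nyquist keeps its amplitude within a fraction of a percent, and
#' content above the output Nyquist is removed entirely.
#'
#' @param w a [waveform()].
#' @param target_fs target sampling rate in Hz (> 0).
#' @return A [waveform()] with `round(length * target_fs / fs)` samples.
#' @export
resample_waveform <- function(w, target_fs) {
  if (!is.numeric(target_fs) || length(target_fs) != 1L || target_fs <= 0)
    stop("target_fs must be a single positive number")
  if (target_fs == w$fs) return(w)
  x <- w$samples
  n_in <- length(x)
  n_out <- round(n_in * target_fs / w$fs)
  X <- stats::fft(x)
  Y <- complex(n_out)
  half <- min(n_in, n_out)
  keep_pos <- seq_len(ceiling(half / 2))          # DC .. positive freqs
  keep_neg <- seq_len(floor((half - 1) / 2))      # negative freqs
  Y[keep_pos] <- X[keep_pos]
  if (length(keep_neg))
    Y[n_out - keep_neg + 1L] <- X[n_in - keep_neg + 1L]
  # when downsampling to an even length, the Nyquist bin pair must stay real
  if (n_out < n_in && n_out %% 2L == 0L)
    Y[n_out / 2 + 1L] <- Re(Y[n_out / 2 + 1L])
  y <- Re(stats::fft(Y, inverse = TRUE)) / n_in
  waveform(y, target_fs, w$channel, w$t0)
}

#' Read / write annotation CSV
#'
#' The annotation interchange format is a CSV with header `label,time_s`
#' where `label` is one of `S1`, `S2`, `SYS_PEAK` and `time_s` is seconds
#' from recording start. A write-then-read round trip reproduces the set
#' exactly (times are printed with 9 decimal places).
#'
#' @param path file path.
#' @return [read_annotations()] returns an [annotation_set()].
#' @export
read_annotations <- function(path) {
  d <- utils::read.csv(path, colClasses = c("character", "numeric"))
  if (!all(c("label", "time_s") %in% names(d)))
    stop("annotation CSV must have columns label,time_s")
  bad <- setdiff(unique(d$label), c("S1", "S2", "SYS_PEAK"))
  if (length(bad)) stop("unknown annotation label(s): ",
                        paste(bad, collapse = ", "))
  annotation_set(s1_times = d$time_s[d$label == "S1"],
                 s2_times = d$time_s[d$label == "S2"],
                 systolic_peak_times = d$time_s[d$label == "SYS_PEAK"])
}

#' @param a an [annotation_set()].
#' @rdname read_annotations
#' @export
write_annotations <- function(a, path) {
  stopifnot(inherits(a, "annotation_set"))
  d <- data.frame(
    label = c(rep("S1", length(a$s1_times)), rep("S2", length(a$s2_times)),
              rep("SYS_PEAK", length(a$systolic_peak_times))),
    time_s = sprintf("%.9f", c(a$s1_times, a$s2_times,
                               a$systolic_peak_times)))
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
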