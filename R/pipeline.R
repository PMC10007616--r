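# End-to-end orchestration of the three model variants.

#' Model configuration
#'
#' The three variants of the detection pipeline:
#' \describe{
#'   \item{I}{plain pipeline on the whole recording,}
#'   \item{II}{pipeline applied per window (default 10 s, non-overlapping),
#'     so thresholds and normalisation adapt to local amplitude,}
#'   \item{III}{windowed pipeline plus envelope filtering, which raises S2
#'     bursts to the S1 amplitude level before detection.}
#' }
#' Variant I must not carry a segment plan or EF settings; variant II a
#' segment plan but no EF; variant III both.
#'
#' The entropy smoothing window defaults to 0.091 s, the S1 burst-duration
#' scale: it integrates the entropy of a whole burst (so the resulting
#' bump height reflects burst energy, which is what separates unboosted S2
#' from S1) while keeping the trace sparse enough for the mean-based
#' impulse threshold; see the methods vignette for the calibration.
#'
#' @param variant `"I"`, `"II"` or `"III"`.
#' @param bandpass a [bandpass_spec()] for the acoustic preprocessing
#'   (default 20-200 Hz, order 4).
#' @param segment a [segment_plan()] or `NULL`; defaults to 10 s windows
#'   for variants II and III.
#' @param ef_delta envelope-filter threshold multiplier (variant III;
#'   default 2).
#' @param ef_band envelope-filter band: low-pass cutoff in Hz or a
#'   [bandpass_spec()] (variant III; default 40 Hz low-pass).
#' @param entropy_window_s,entropy_polyorder Savitzky-Golay smoothing of
#'   the entropy trace (defaults 0.091 s, order 3).
#' @param sigma impulse threshold multiplier (default 5).
#' @param vtt a [vtt_config()]; by default `onset_lead_s` is set to half
#'   the entropy window plus the 25 ms systolic-peak refinement
#'   half-window -- the two systematic timing slacks between detected
#'   burst start points and the sounds the nominal VTT refers to.
#' @param eval_tol_s event-matching tolerance used by [evaluate_run()]
#'   (default 0.060).
#' @param min_gap_s minimum start-point spacing (default 0.100).
#' @param dedup_s cross-segment duplicate window (default 0.050).
#' @return An object of class `model_config`.
#' @export
model_config <- function(variant = c("III", "I", "II"),
                         bandpass = bandpass_spec(20, 200, 4),
                         segment = NULL, ef_delta = NULL, ef_band = NULL,
                         entropy_window_s = 0.091, entropy_polyorder = 3,
                         sigma = 5, vtt = NULL, eval_tol_s = 0.060,
                         min_gap_s = 0.100, dedup_s = 0.050) {
  variant <- match.arg(variant)
  if (variant %in% c("II", "III") && is.null(segment))
    segment <- segment_plan(10, 0)
  if (variant == "III") {
    if (is.null(ef_delta)) ef_delta <- 2
    if (is.null(ef_band)) ef_band <- 40
  }
  if (variant == "I" && !is.null(segment))
    stop("variant I does not use segmentation")
  if (variant %in% c("I", "II") && !is.null(ef_delta))
    stop("variant ", variant, " does not use envelope filtering")
  if (variant %in% c("II", "III") && is.null(segment))
    stop("variant ", variant, " requires a segment plan")
  if (is.null(vtt))
    vtt <- vtt_config(onset_lead_s = entropy_window_s / 2 + 0.025)
  structure(list(variant = variant, bandpass = bandpass, segment = segment,
                 ef_delta = ef_delta, ef_band = ef_band,
                 entropy_window_s = entropy_window_s,
                 entropy_polyorder = entropy_polyorder, sigma = sigma,
                 vtt = vtt, eval_tol_s = eval_tol_s,
                 min_gap_s = min_gap_s, dedup_s = dedup_s),
            class = "model_config")
}

# PCG detection on one segment: band-pass -> [EF] -> entropy of the
# normalised instantaneous energy -> Savitzky-Golay -> min-max ->
# sigma * mean impulse threshold -> start points.
.detect_segment <- function(seg, cfg) {
  xf <- .bandpass_num(seg$samples, seg$fs, cfg$bandpass)
  work <- if (cfg$variant == "III") {
    ae <- analytic_transform(waveform(xf, seg$fs, "PCG", seg$t0))
    envelope_filter(ae, delta = cfg$ef_delta, band = cfg$ef_band)$z
  } else {
    xf
  }
  se <- shannon_entropy(work^2)
  sm <- smooth_entropy(se, seg$fs, cfg$entropy_window_s,
                       cfg$entropy_polyorder)
  nse <- normalize_minmax(pmax(sm, 0))
  it <- impulse_detect(nse, sigma = cfg$sigma, fs = seg$fs)
  cand <- extract_startpoints(it, t0 = seg$t0, min_gap_s = cfg$min_gap_s)
  amp <- if (length(it$start_indices)) nse[it$start_indices] else numeric()
  # amplitudes must follow the same merge as the times
  kept <- match(cand$times, (it$start_indices - 1) / seg$fs + seg$t0)
  cand$amplitudes <- amp[kept]
  cand
}

#' Run a detection model on a recording
#'
#' Executes the full dual pipeline: acoustic band-pass, optional windowed
#' segmentation, optional envelope filtering, Shannon-entropy peak
#' enhancement, Savitzky-Golay smoothing, min-max normalisation, impulse
#' thresholding and start-point extraction on the PCG; systolic-peak
#' detection on the PPG; then VTT fusion labelling ([classify_heart_sounds()])
#' and S2 revalidation ([refine_s2()]). Segment-local times are mapped to
#' absolute time, and duplicate events from overlapping windows are
#' removed.
#'
#' @param rec a [recording()].
#' @param cfg a [model_config()].
#' @return A `labeled_heart_sounds` object; the events data frame has
#'   columns `time`, `label`, `matched_peak_time`, `confidence`.
#' @export
run_model <- function(rec, cfg = model_config("III")) {
  stopifnot(inherits(rec, "recording"), inherits(cfg, "model_config"))
  if (cfg$variant == "I" && !is.null(cfg$segment))
    stop("variant I must not carry a segment plan")
  if (cfg$variant %in% c("II", "III") && is.null(cfg$segment))
    stop("variant ", cfg$variant, " requires a segment plan")
  if (cfg$variant %in% c("I", "II") && !is.null(cfg$ef_delta))
    stop("variant ", cfg$variant, " must not carry envelope-filter settings")
  if (cfg$variant == "III" && is.null(cfg$ef_delta))
    stop("variant III requires envelope-filter settings")
  need <- round(cfg$entropy_window_s * rec$pcg$fs)
  if (length(rec$pcg$samples) < need + 1L)
    stop("recording shorter than one entropy smoothing window")
  segs <- if (is.null(cfg$segment)) list(rec$pcg)
          else segment_waveform(rec$pcg, cfg$segment)
  parts <- lapply(segs, .detect_segment, cfg = cfg)
  cands <- merge_candidates(parts, dedup_s = cfg$dedup_s,
                            amplitudes = lapply(parts,
                                                function(p) p$amplitudes))
  peaks <- detect_systolic_peaks(rec$ppg)
  labeled <- classify_heart_sounds(cands, peaks, cfg$vtt)
  refine_s2(labeled, peaks, cfg$vtt)
}

#' Score a labelled detection run against reference annotations
#'
#' S1 and S2 events are scored separately with [match_events()] at the
#' configured tolerance and summarised with [compute_metrics()]. The
#' returned row mirrors the study's per-subject table layout.
#'
#' @param labeled a [run_model()] result.
#' @param truth an [annotation_set()] with non-empty S1 and S2 lists.
#' @param cfg the [model_config()] used for the run.
#' @param span optional `(t_start, t_end)` record span.
#' @param subject optional subject identifier for the report row.
#' @return List with `s1` and `s2` (each `list(counts, metrics)`) and
#'   `row`, a one-row data frame with columns `subject`, `mean_hr_bpm`,
#'   and per-sound counts and metrics.
#' @export
evaluate_run <- function(labeled, truth, cfg, span = NULL, subject = "") {
  stopifnot(inherits(labeled, "labeled_heart_sounds"),
            inherits(truth, "annotation_set"))
  if (!length(truth$s1_times) && !length(truth$s2_times))
    stop("reference annotations are empty")
  ev <- labeled$events
  score <- function(lab, ref) {
    cc <- match_events(ev$time[ev$label == lab], ref,
                       tol_s = cfg$eval_tol_s, span = span)
    list(counts = cc, metrics = compute_metrics(cc))
  }
  s1 <- score("S1", truth$s1_times)
  s2 <- score("S2", truth$s2_times)
  hr <- if (length(truth$s1_times) > 1L)
    60 / mean(diff(truth$s1_times)) else NA_real_
  row <- data.frame(subject = subject, mean_hr_bpm = hr,
                    s1_tp = s1$counts$tp, s1_tn = s1$counts$tn,
                    s1_fp = s1$counts$fp, s1_fn = s1$counts$fn,
                    s1_sen = s1$metrics$sen, s1_pre = s1$metrics$pre,
                    s1_spe = s1$metrics$spe, s1_acc = s1$metrics$acc,
                    s2_tp = s2$counts$tp, s2_tn = s2$counts$tn,
                    s2_fp = s2$counts$fp, s2_fn = s2$counts$fn,
                    s2_sen = s2$metrics$sen, s2_pre = s2$metrics$pre,
                    s2_spe = s2$metrics$spe, s2_acc = s2$metrics$acc)
  list(s1 = s1, s2 = s2, row = row)
}
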