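# Dual-deterministic fusion: label PCG candidates S1/S2 from PPG systolic
# peaks via the vascular transit time (VTT) interval rule.

#' VTT fusion configuration
#'
#' The pressure pulse needs the vascular transit time (nominally ~200 ms)
#' to travel from the heart to the finger, so the S1 that opens a beat
#' precedes "its" systolic peak by roughly VTT, while S2 closes the beat
#' about 300 ms later, near the systolic peak itself. A PCG candidate at
#' time `T` is labelled S1 when
#' `T_peak - vtt_s - onset_lead_s <= T <= T_peak - beta_s`
#' for the nearest following systolic peak, and S2 otherwise.
#'
#' `onset_lead_s` widens the window's lower bound to absorb the systematic
#' lead of detected burst *start points* relative to the sound the nominal
#' VTT refers to; with the default 0 the interval rule is applied exactly
#' as stated.
#'
#' @param vtt_s vascular transit time in seconds (default 0.200).
#' @param beta_s upper-bound margin in seconds (default 0.100).
#' @param s2_window_s S2-to-systolic-peak confirmation window used by
#'   [refine_s2()] (default 0.020).
#' @param onset_lead_s start-point lead allowance in seconds (default 0).
#' @return An object of class `vtt_config`.
#' @export
vtt_config <- function(vtt_s = 0.200, beta_s = 0.100, s2_window_s = 0.020,
                       onset_lead_s = 0) {
  if (!(beta_s > 0 && beta_s < vtt_s))
    stop("need 0 < beta_s < vtt_s")
  if (onset_lead_s < 0) stop("onset_lead_s must be nonnegative")
  structure(list(vtt_s = vtt_s, beta_s = beta_s, s2_window_s = s2_window_s,
                 onset_lead_s = onset_lead_s),
            class = "vtt_config")
}

#' Label heart-sound candidates S1 or S2 using systolic-peak timing
#'
#' For each candidate the nearest following systolic peak within
#' `vtt_s + 0.1 + onset_lead_s` seconds is sought. If one exists, the VTT
#' interval rule labels the candidate S1 when it falls inside the closed
#' window `[peak - vtt_s - onset_lead_s, peak - beta_s]` and S2 otherwise.
#' When two candidates satisfy the S1 window for the same peak, the
#' earlier keeps S1 and the later becomes S2 (one S1 per cardiac cycle).
#'
#' Candidates with no peak in scope (including the case of an empty peak
#' list, which raises a warning) are labelled by fallback: alternation
#' relative to the nearest preceding labelled event when it lies within
#' 0.6 s, otherwise by the amplitude heuristic (the larger of the first
#' pair is S1) when amplitudes are available, otherwise S2.
#'
#' @param cands a `heart_sound_candidates` object (optionally carrying
#'   `amplitudes`).
#' @param peaks a [detect_systolic_peaks()] result.
#' @param cfg a [vtt_config()].
#' @return An object of class `labeled_heart_sounds`: a data frame
#'   `events` with columns `time`, `label` and `matched_peak_time` (NA
#'   where no peak justified the label).
#' @export
classify_heart_sounds <- function(cands, peaks, cfg = vtt_config()) {
  stopifnot(inherits(cands, "heart_sound_candidates"),
            inherits(cfg, "vtt_config"))
  tc <- cands$times
  tp <- peaks$times
  n <- length(tc)
  label <- rep(NA_character_, n)
  matched <- rep(NA_real_, n)
  scope <- cfg$vtt_s + 0.1 + cfg$onset_lead_s
  if (!length(tp) && n) {
    warning("no systolic peaks: labelling all candidates by fallback")
  } else {
    for (i in seq_len(n)) {
      fol <- tp[tp >= tc[i]]
      if (!length(fol) || fol[1L] - tc[i] > scope) next
      p <- fol[1L]
      matched[i] <- p
      lo <- p - cfg$vtt_s - cfg$onset_lead_s
      hi <- p - cfg$beta_s
      # closed interval with a nanosecond slack against float round-off
      label[i] <- if (tc[i] >= lo - 1e-9 && tc[i] <= hi + 1e-9) "S1" else "S2"
    }
    # one S1 per peak: demote later duplicates to S2
    s1_idx <- which(label == "S1")
    if (length(s1_idx) > 1L) {
      for (p in unique(matched[s1_idx])) {
        grp <- s1_idx[!is.na(matched[s1_idx]) & matched[s1_idx] == p]
        if (length(grp) > 1L) label[grp[-1L]] <- "S2"
      }
    }
  }
  # fallback for unresolved candidates
  amps <- cands$amplitudes
  for (i in seq_len(n)) {
    if (!is.na(label[i])) next
    prev <- if (i > 1L) label[i - 1L] else NA_character_
    if (!is.na(prev) && (tc[i] - tc[i - 1L]) < 0.6) {
      label[i] <- if (prev == "S1") "S2" else "S1"
    } else if (!is.null(amps) && i < n) {
      label[i] <- if (amps[i] >= amps[i + 1L]) "S1" else "S2"
    } else {
      label[i] <- "S2"
    }
  }
  structure(list(events = data.frame(time = tc, label = label,
                                     matched_peak_time = matched)),
            class = "labeled_heart_sounds")
}

#' @export
print.labeled_heart_sounds <- function(x, ...) {
  tab <- table(x$events$label)
  cat(sprintf("<labeled_heart_sounds> %d events (%s)\n", nrow(x$events),
              paste(names(tab), tab, sep = ": ", collapse = ", ")))
  invisible(x)
}

#' Revalidate S2 labels against systolic-peak proximity
#'
#' S2 occurs within about 20 ms of the PPG systolic peak, so S2 events
#' farther than `s2_window_s + slack_s` from every peak are flagged
#' low-confidence (they are retained, not dropped); S2 events within the
#' window are confirmed. S1 events are not affected.
#'
#' @param labeled a [classify_heart_sounds()] result.
#' @param peaks a [detect_systolic_peaks()] result.
#' @param cfg a [vtt_config()].
#' @param slack_s additional tolerance around `s2_window_s` (default
#'   0.030).
#' @return The input with an added `confidence` column: `"confirmed"` or
#'   `"low"` for S2 rows, `NA` for S1 rows.
#' @export
refine_s2 <- function(labeled, peaks, cfg = vtt_config(), slack_s = 0.030) {
  stopifnot(inherits(labeled, "labeled_heart_sounds"))
  ev <- labeled$events
  conf <- rep(NA_character_, nrow(ev))
  win <- cfg$s2_window_s + slack_s
  for (i in which(ev$label == "S2")) {
    conf[i] <- if (length(peaks$times) &&
                   min(abs(peaks$times - ev$time[i])) <= win)
      "confirmed" else "low"
  }
  ev$confidence <- conf
  labeled$events <- ev
  labeled
}
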