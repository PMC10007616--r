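# Event-detection scoring: tolerance matching, confusion counts,
# sensitivity / precision / specificity / accuracy, cohort aggregation.

#' Match detected events to reference events
#'
#' Computes confusion counts for event detection on a time axis. Detected
#' and reference times are paired one-to-one within a tolerance `tol_s`
#' using the maximum-cardinality non-crossing matching (dynamic programming
#' over the two sorted lists; on a line with a tolerance an optimal
#' matching can always be uncrossed, so this attains the bipartite
#' optimum). Matched pairs are true positives; unmatched detections false
#' positives; unmatched references false negatives.
#'
#' True negatives in continuous time are counted over decision slots: the
#' record is partitioned at every reference event and at every midpoint
#' between consecutive reference events (plus the record edges), giving
#' half-beat slots. Slots not beginning with a reference event and not
#' containing any unmatched detection (false positive) are the true
#' negatives; matched detections belong to their reference's event slot
#' regardless of which side of it they fall on.
#'
#' @param detected,reference numeric vectors of event times in seconds
#'   (sorted; unsorted input is sorted with a warning).
#' @param tol_s matching tolerance in seconds (> 0); default 60 ms, below
#'   half the minimum S1-S2 separation.
#' @param span two-element `(t_start, t_end)` record span; defaults to the
#'   range of all supplied times.
#' @return An object of class `confusion_counts` with fields `tp`, `tn`,
#'   `fp`, `fn`.
#' @export
match_events <- function(detected, reference, tol_s = 0.060, span = NULL) {
  if (tol_s <= 0) stop("tol_s must be positive")
  if (is.unsorted(detected)) {
    warning("detected times unsorted; sorting")
    detected <- sort(detected)
  }
  if (is.unsorted(reference)) {
    warning("reference times unsorted; sorting")
    reference <- sort(reference)
  }
  if (is.null(span)) span <- range(c(detected, reference, 0))
  nd <- length(detected)
  nr <- length(reference)
  # DP over sorted lists: f[i+1, j+1] = best matching of detected[1..i],
  # reference[1..j]
  f <- matrix(0L, nd + 1L, nr + 1L)
  for (i in seq_len(nd)) {
    for (j in seq_len(nr)) {
      best <- max(f[i, j + 1L], f[i + 1L, j])
      if (abs(detected[i] - reference[j]) <= tol_s)
        best <- max(best, f[i, j] + 1L)
      f[i + 1L, j + 1L] <- best
    }
  }
  tp <- f[nd + 1L, nr + 1L]
  fp <- nd - tp
  fn <- nr - tp
  # backtrack one optimal matching to identify the unmatched detections
  matched_det <- rep(FALSE, nd)
  i <- nd; j <- nr
  while (i > 0L && j > 0L) {
    if (abs(detected[i] - reference[j]) <= tol_s &&
        f[i + 1L, j + 1L] == f[i, j] + 1L) {
      matched_det[i] <- TRUE
      i <- i - 1L; j <- j - 1L
    } else if (f[i + 1L, j + 1L] == f[i, j + 1L]) {
      i <- i - 1L
    } else {
      j <- j - 1L
    }
  }
  tn <- .count_true_negatives(detected[!matched_det], reference, span)
  structure(list(tp = tp, tn = tn, fp = fp, fn = fn),
            class = "confusion_counts")
}

# decision slots: boundaries at record edges, reference events and
# midpoints between consecutive references; slots whose left edge is not a
# reference and which contain no detection count as true negatives.
.count_true_negatives <- function(detected, reference, span) {
  if (!length(reference)) {
    return(as.integer(!length(detected)))
  }
  mids <- if (length(reference) > 1L)
    (reference[-1L] + reference[-length(reference)]) / 2 else numeric()
  bounds <- sort(unique(c(span[1], reference, mids, span[2])))
  tn <- 0L
  for (k in seq_len(length(bounds) - 1L)) {
    lo <- bounds[k]
    hi <- bounds[k + 1L]
    if (any(abs(reference - lo) < 1e-12)) next       # event slot
    if (!any(detected >= lo & detected < hi)) tn <- tn + 1L
  }
  tn
}

#' Detection metrics from confusion counts
#'
#' Sensitivity `SEN = TP / (TP + FN)`, precision `PRE = TP / (TP + FP)`,
#' specificity `SPE = TN / (TN + FP)` and accuracy
#' `ACC = (TP + TN) / (TP + TN + FP + FN)`, each as a percentage. A metric
#' whose denominator is zero is returned as `NA`.
#'
#' @param cc a [match_events()] result, or any list with fields `tp`,
#'   `tn`, `fp`, `fn`.
#' @return An object of class `metrics_report` with fields `sen`, `pre`,
#'   `spe`, `acc` (percent).
#' @export
compute_metrics <- function(cc) {
  tp <- cc$tp; tn <- cc$tn; fp <- cc$fp; fn <- cc$fn
  if (any(c(tp, tn, fp, fn) < 0)) stop("counts must be nonnegative")
  if (tp + tn + fp + fn == 0) stop("all counts are zero")
  rat <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  structure(list(sen = rat(tp, tp + fn),
                 pre = rat(tp, tp + fp),
                 spe = rat(tn, tn + fp),
                 acc = rat(tp + tn, tp + tn + fp + fn)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("SEN %.2f  PRE %.2f  SPE %.2f  ACC %.2f (%%)\n",
              x$sen, x$pre, x$spe, x$acc))
  invisible(x)
}

#' Aggregate per-subject metric reports
#'
#' Per-metric arithmetic mean and sample standard deviation (n - 1) over a
#' cohort, the convention of per-subject summary rows.
#'
#' @param reports non-empty list of [compute_metrics()] results.
#' @return List with `mean` and `sd`, each a `metrics_report`.
#' @export
aggregate_metrics <- function(reports) {
  if (!length(reports)) stop("empty report list")
  get <- function(f) vapply(reports, function(r) r[[f]], numeric(1))
  mk <- function(fun) structure(
    list(sen = fun(get("sen")), pre = fun(get("pre")),
         spe = fun(get("spe")), acc = fun(get("acc"))),
    class = "metrics_report")
  sd1 <- function(v) if (length(v) > 1L) stats::sd(v, na.rm = TRUE) else 0
  list(mean = mk(function(v) mean(v, na.rm = TRUE)), sd = mk(sd1))
}

#' Reported per-subject detection counts of the study cohort
#'
#' The package ships the published per-subject event-detection counts
#' (TP/TN/FP/FN) and scores (SEN/PRE/SPE/ACC, percent) of the 20-subject
#' study cohort, for each model variant (I: plain pipeline, II: windowed,
#' III: windowed + envelope filter) and heart sound. They serve to
#' validate the metric arithmetic and the model comparisons.
#'
#' @param model `"I"`, `"II"` or `"III"`.
#' @param sound `"S1"` or `"S2"`.
#' @param summary_rows keep the `AVG` / `STD` rows? (default drops them).
#' @return Data frame with columns `subject`, `mean_hr_bpm`, `tp`, `tn`,
#'   `fp`, `fn`, `sen`, `pre`, `spe`, `acc`.
#' @export
reference_detection_counts <- function(model = c("I", "II", "III"),
                                       sound = c("S1", "S2"),
                                       summary_rows = FALSE) {
  model <- match.arg(model)
  sound <- match.arg(sound)
  fname <- sprintf("model%d_%s.csv", match(model, c("I", "II", "III")),
                   tolower(sound))
  path <- system.file("extdata", "reference_counts", fname,
                      package = "ddmhsa", mustWork = TRUE)
  d <- utils::read.csv(path, colClasses = c(subject = "character"))
  if (!summary_rows) d <- d[!(d$subject %in% c("AVG", "STD")), ]
  d
}
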