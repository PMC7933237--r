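# Pretraining label rules. All windows are half-open `[start, start+length)`
# in 0-based samples.

HR_CLASSES <- c("BRADY", "NORMAL", "TACHY", "NOISE")

unlabelable <- function(msg) {
  stop(structure(class = c("ecgtl_unlabelable", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

no_rate <- function(msg) {
  stop(structure(class = c("ecgtl_no_rate", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' Beat label of a frame
#'
#' Counts the abnormal beat classes (PAC, PVC, aberration) among annotated
#' beats inside the window; returns the most frequent abnormal class, or
#' NORMAL if no abnormal beat is present. Count ties break by the fixed
#' priority PVC > PAC > ABERRATION. A frame containing no annotated beat is
#' unlabelable (this task has no noise category); the caller resamples.
#'
#' @param fr a [frame()]
#' @param beats beat annotation data.frame (`sample`, `class`)
#' @return one of NORMAL/PAC/PVC/ABERRATION
#' @export
label_beat <- function(fr, beats) {
  inside <- beats$sample >= fr$start & beats$sample < fr$start + fr$length
  if (!any(inside)) unlabelable("no annotated beat inside frame")
  cls <- beats$class[inside]
  priority <- c("PVC", "PAC", "ABERRATION")
  counts <- vapply(priority, function(p) sum(cls == p), 0L)
  if (all(counts == 0L)) return("NORMAL")
  priority[which.max(counts)]  # which.max takes the first maximum = priority order
}

#' Rhythm label of a frame
#'
#' Per-class durations are the overlap lengths of the rhythm intervals with
#' the frame window. If atrial fibrillation or flutter overlap the frame at
#' all, the longer of the two is returned (tie: AFIB); otherwise the longest
#' of the remaining rhythms (normal sinus rhythm or noise; tie: NSR).
#'
#' @param fr a [frame()]
#' @param rhythms rhythm interval data.frame (`start`, `end`, `class`)
#' @return one of NSR/AFIB/AFLUT/NOISE
#' @export
label_rhythm <- function(fr, rhythms) {
  lo <- pmax(rhythms$start, fr$start)
  hi <- pmin(rhythms$end, fr$start + fr$length)
  ov <- pmax(hi - lo, 0)
  if (sum(ov) == 0) stop("frame overlaps no rhythm interval (broken tiling)")
  dur <- vapply(RHYTHM_CLASSES, function(cl) sum(ov[rhythms$class == cl]), 0)
  if (dur[["AFIB"]] > 0 || dur[["AFLUT"]] > 0) {
    if (dur[["AFIB"]] >= dur[["AFLUT"]]) "AFIB" else "AFLUT"
  } else {
    if (dur[["NSR"]] >= dur[["NOISE"]]) "NSR" else "NOISE"
  }
}

#' Heart-rate estimate from beat indices
#'
#' BPM = 60 / mean interbeat interval in seconds (the simplest unbiased
#' estimator consistent with labeling from interbeat intervals).
#'
#' @param beat_indices strictly increasing sample indices
#' @param fs sampling frequency in Hz
#' @return BPM as a real number; fewer than 2 beats signals a `no rate`
#'   condition (class `ecgtl_no_rate`)
#' @export
estimate_bpm <- function(beat_indices, fs) {
  if (length(beat_indices) < 2L) no_rate("need at least 2 beats to estimate a rate")
  60 / mean(diff(beat_indices) / fs)
}

#' Heart-rate labeling rule
#' @param brady_upper exclusive upper BPM bound of bradycardia (default 60)
#' @param tachy_lower exclusive lower BPM bound of tachycardia (default 100)
#' @param window_pad_s seconds added to each side of the frame when labeling
#' @export
heart_rate_rule <- function(brady_upper = 60, tachy_lower = 100, window_pad_s = 1) {
  if (brady_upper >= tachy_lower) stop("brady_upper must be below tachy_lower")
  if (window_pad_s < 0) stop("window_pad_s must be >= 0")
  list(brady_upper = brady_upper, tachy_lower = tachy_lower,
       window_pad_s = window_pad_s)
}

#' Heart-rate label of a frame
#'
#' The frame is temporarily extended by 1 s on each side (clipped at the
#' segment bounds), beats inside the padded window are found from the chosen
#' source, and the class follows the BPM: below 60 bradycardia, above 100
#' tachycardia, 60-100 inclusive normal. Fewer than 2 beats (no estimable
#' rate) labels the frame as noise.
#'
#' @param fr a [frame()]
#' @param rec the frame's [annotated_recording()]
#' @param rule a [heart_rate_rule()]
#' @param beat_source `"ground_truth"` (annotated beats) or `"detector"`
#'   ([detect_beats()])
#' @return one of BRADY/NORMAL/TACHY/NOISE
#' @export
label_heart_rate <- function(fr, rec, rule = heart_rate_rule(),
                             beat_source = c("ground_truth", "detector")) {
  beat_source <- match.arg(beat_source)
  pad <- round(rule$window_pad_s * rec$fs)
  lo <- max(0L, fr$start - pad)
  hi <- min(length(rec$signal), fr$start + fr$length + pad)
  beats <- if (beat_source == "ground_truth") {
    b <- rec$beats$sample
    b[b >= lo & b < hi]
  } else {
    lo + detect_beats(rec$signal[(lo + 1L):hi], rec$fs)
  }
  if (length(beats) < 2L) return("NOISE")
  bpm <- estimate_bpm(beats, rec$fs)
  if (bpm < rule$brady_upper) "BRADY"
  else if (bpm > rule$tachy_lower) "TACHY"
  else "NORMAL"
}
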