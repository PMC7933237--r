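#' Construct an annotated recording
#'
#' A continuous single-lead signal with beat annotations (0-based sample
#' index + beat class) and rhythm intervals (0-based, half-open, sorted,
#' non-overlapping, jointly tiling the whole signal).
#'
#' @param signal numeric vector
#' @param fs sampling frequency in Hz
#' @param beats data.frame with columns `sample` (0-based integer) and
#'   `class` (one of NORMAL/PAC/PVC/ABERRATION)
#' @param rhythms data.frame with columns `start`, `end` (0-based, half-open)
#'   and `class` (one of NSR/AFIB/AFLUT/NOISE)
#' @param patient_id,segment_id identifiers
#' @return an `annotated_recording`
#' @export
annotated_recording <- function(signal, fs, beats, rhythms,
                                patient_id = "p00000", segment_id = "s00") {
  beats$sample <- as.integer(beats$sample)
  rhythms$start <- as.integer(rhythms$start)
  rhythms$end <- as.integer(rhythms$end)
  rec <- structure(list(patient_id = patient_id, segment_id = segment_id,
                        signal = as.numeric(signal), fs = fs,
                        beats = beats, rhythms = rhythms),
                   class = "annotated_recording")
  validate_recording(rec)
  rec
}

#' Validate the invariants of an annotated recording
#' @param rec an `annotated_recording`
#' @return the recording, invisibly; errors describe the violated invariant
#' @export
validate_recording <- function(rec) {
  n <- length(rec$signal)
  if (!is.numeric(rec$fs) || rec$fs <= 0) stop("fs must be positive")
  b <- rec$beats
  if (nrow(b) > 0) {
    if (any(diff(b$sample) <= 0)) stop("beat indices must be strictly increasing")
    if (any(b$sample < 0) || any(b$sample >= n)) stop("beat index out of signal range")
    if (!all(b$class %in% BEAT_CLASSES)) stop("unknown beat class")
  }
  r <- rec$rhythms
  if (nrow(r) == 0) stop("rhythm intervals must cover the signal")
  if (!all(r$class %in% RHYTHM_CLASSES)) stop("unknown rhythm class")
  if (r$start[1] != 0 || r$end[nrow(r)] != n ||
      (nrow(r) > 1 && any(r$start[-1] != r$end[-nrow(r)])))
    stop("rhythm intervals must tile [0, signal length) without gaps or overlaps")
  if (any(r$end <= r$start)) stop("rhythm intervals must be non-empty")
  invisible(rec)
}

#' @export
print.annotated_recording <- function(x, ...) {
  cat(sprintf("<annotated_recording %s/%s: %.1f s @ %g Hz, %d beats, %d rhythm intervals>\n",
              x$patient_id, x$segment_id, length(x$signal) / x$fs, x$fs,
              nrow(x$beats), nrow(x$rhythms)))
  invisible(x)
}

# Gaussian bump added in place over its +-4 sd support
add_bump <- function(signal, center_s, amp, sd_s, fs) {
  n <- length(signal)
  lo <- max(1L, floor((center_s - 4 * sd_s) * fs) + 1L)
  hi <- min(n, ceiling((center_s + 4 * sd_s) * fs) + 1L)
  if (lo > hi) return(signal)
  t <- (seq(lo, hi) - 1) / fs
  signal[lo:hi] <- signal[lo:hi] + amp * exp(-0.5 * ((t - center_s) / sd_s)^2)
  signal
}

# Draw one interbeat interval (seconds) for a rhythm class
draw_ibi <- function(rhythm, gp, base_bpm) {
  base <- switch(rhythm,
    NSR = 60 / base_bpm,
    AFIB = 60 / gp$afib_bpm,
    AFLUT = 60 / gp$aflut_bpm)
  cv <- switch(rhythm, NSR = gp$nsr_jitter_cv, AFIB = gp$afib_ibi_cv,
               AFLUT = gp$aflut_jitter_cv)
  if (cv <= 0) return(base)
  sdlog <- sqrt(log(1 + cv^2))
  max(0.2, base * stats::rlnorm(1, meanlog = -sdlog^2 / 2, sdlog = sdlog))
}

band_limited_noise <- function(n, amp, fs) {
  w <- stats::rnorm(n + 20)
  k <- max(3L, round(fs / 40))
  sm <- stats::filter(w, rep(1 / k, k), sides = 2)
  sm <- sm[10 + seq_len(n)]
  sm[is.na(sm)] <- 0
  amp * sm / max(stats::sd(sm), 1e-12)
}

#' Render a beat train following a rhythm plan
#'
#' Per-beat waveform template: a Gaussian QRS bump with smaller P and T
#' bumps. PVCs are widened, high-amplitude QRS complexes without a P wave
#' followed by a compensatory pause; PACs arrive early; aberrant beats are
#' widened with reduced amplitude and an inverted T wave. AFib episodes have
#' irregular interbeat intervals and no P waves; NOISE episodes are
#' band-limited noise with no beats. The returned ground truth exactly
#' describes the rendered signal.
#'
#' @param rhythm_plan data.frame with columns `class` and `duration_s`, or a
#'   list of `(class, duration_s)` pairs
#' @param gen_params a [gen_params()] object
#' @param fs sampling frequency in Hz
#' @param base_bpm baseline sinus BPM for this recording; defaults to
#'   `gen_params$nsr_bpm` or the midpoint of `nsr_bpm_range`
#' @param patient_id,segment_id identifiers stored in the recording
#' @return an [annotated_recording()]
#' @export
render_beat_train <- function(rhythm_plan, gen_params = NULL, fs = 250,
                              base_bpm = NULL, patient_id = "p00000",
                              segment_id = "s00") {
  gp <- if (is.null(gen_params)) default_gen_params() else gen_params
  if (is.list(rhythm_plan) && !is.data.frame(rhythm_plan))
    rhythm_plan <- data.frame(class = vapply(rhythm_plan, `[[`, "", 1),
                              duration_s = vapply(rhythm_plan, function(e) as.numeric(e[[2]]), 0))
  if (nrow(rhythm_plan) == 0) stop("rhythm plan must be non-empty")
  if (any(rhythm_plan$duration_s <= 0)) stop("episode durations must be positive")
  if (!all(rhythm_plan$class %in% RHYTHM_CLASSES)) stop("unknown rhythm class in plan")
  if (fs <= 0) stop("fs must be positive")
  if (is.null(base_bpm))
    base_bpm <- if (!is.null(gp$nsr_bpm)) gp$nsr_bpm else mean(gp$nsr_bpm_range)

  ep_samples <- round(rhythm_plan$duration_s * fs)
  ends <- cumsum(ep_samples)
  starts <- c(0, ends[-length(ends)])
  n <- ends[length(ends)]
  signal <- numeric(n)
  beat_sample <- integer(0)
  beat_class <- character(0)

  for (e in seq_len(nrow(rhythm_plan))) {
    rhythm <- rhythm_plan$class[e]
    t0 <- starts[e] / fs
    t1 <- ends[e] / fs
    if (rhythm == "NOISE") {
      idx <- (starts[e] + 1L):ends[e]
      signal[idx] <- signal[idx] + band_limited_noise(length(idx), gp$noise_amp, fs)
      next
    }
    t <- t0
    prev_ibi <- draw_ibi(rhythm, gp, base_bpm)
    while (t < t1 - 1e-9) {
      cls <- "NORMAL"
      if (rhythm %in% c("NSR", "AFIB")) {
        u <- stats::runif(1)
        if (u < gp$pvc_rate) cls <- "PVC"
        else if (u < gp$pvc_rate + gp$pac_rate) cls <- "PAC"
        else if (u < gp$pvc_rate + gp$pac_rate + gp$aberration_rate) cls <- "ABERRATION"
      }
      tb <- t
      if (cls == "PAC" && length(beat_sample) > 0) {
        # premature: pull the beat forward by a quarter of the local IBI
        tb <- max(t - 0.25 * prev_ibi,
                  (beat_sample[length(beat_sample)] + 1L) / fs + 0.12)
      }
      s <- round(tb * fs)
      if (s >= ends[e] || s >= n) break
      if (length(beat_sample) > 0 && s <= beat_sample[length(beat_sample)]) {
        t <- t + draw_ibi(rhythm, gp, base_bpm)
        next
      }
      # morphology
      mo <- gp$morph
      if (cls == "PVC") {
        signal <- add_bump(signal, tb, 1.4 * mo$qrs_amp, 2.5 * mo$qrs_sd, fs)
        signal <- add_bump(signal, tb + 0.30, -0.9 * mo$t_amp, mo$t_sd, fs)
      } else if (cls == "ABERRATION") {
        signal <- add_bump(signal, tb, 0.8 * mo$qrs_amp, 2 * mo$qrs_sd, fs)
        signal <- add_bump(signal, tb + 0.25, -mo$t_amp, mo$t_sd, fs)
        if (rhythm != "AFIB") signal <- add_bump(signal, tb - 0.16, 0.8 * mo$p_amp, 0.025, fs)
      } else {
        signal <- add_bump(signal, tb, mo$qrs_amp, mo$qrs_sd, fs)
        signal <- add_bump(signal, tb + 0.25, mo$t_amp, mo$t_sd, fs)
        if (rhythm != "AFIB") signal <- add_bump(signal, tb - 0.16, mo$p_amp, 0.025, fs)
      }
      beat_sample <- c(beat_sample, s)
      beat_class <- c(beat_class, cls)
      ibi <- draw_ibi(rhythm, gp, base_bpm)
      if (cls == "PVC") ibi <- 1.5 * ibi  # compensatory pause
      prev_ibi <- ibi
      t <- t + ibi
    }
    if (rhythm == "AFIB") {
      # coarse fibrillatory baseline instead of P waves
      idx <- (starts[e] + 1L):ends[e]
      tt <- (idx - 1) / fs
      signal[idx] <- signal[idx] + 0.05 * sin(2 * pi * 6 * tt + stats::runif(1, 0, 2 * pi))
    }
  }
  if (gp$baseline_noise > 0) signal <- signal + stats::rnorm(n, sd = gp$baseline_noise)
  annotated_recording(signal, fs,
                      beats = data.frame(sample = beat_sample, class = beat_class,
                                         stringsAsFactors = FALSE),
                      rhythms = data.frame(start = starts, end = ends,
                                           class = rhythm_plan$class,
                                           stringsAsFactors = FALSE),
                      patient_id = patient_id, segment_id = segment_id)
}
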