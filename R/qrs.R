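#' Detect QRS complexes in a single-lead ECG signal
#'
#' A simple energy-based detector: band-pass 5-15 Hz (2nd-order Butterworth,
#' zero-phase), squared derivative, 150 ms moving-window integration, an
#' adaptive amplitude threshold and a 200 ms refractory period. Before
#' accepting any beats, the envelope must look impulsive (envelope peak well
#' above its median); otherwise the segment is treated as beat-free, so
#' noise-only input yields an empty result. Detected peak positions are
#' refined on the band-passed signal.
#'
#' @param signal numeric vector
#' @param fs sampling frequency in Hz (> 0)
#' @return strictly increasing 0-based sample indices of detected QRS peaks
#'   (possibly empty)
#' @export
detect_beats <- function(signal, fs) {
  if (fs <= 0) stop("fs must be positive")
  n <- length(signal)
  if (n < round(0.5 * fs) || all(signal == signal[1])) return(integer(0))
  bf <- signal::butter(2, c(5, 15) / (fs / 2), type = "pass")
  filt <- signal::filtfilt(bf, signal - mean(signal))
  denv <- c(diff(filt), 0)^2
  w <- max(3L, round(0.15 * fs))
  env <- stats::filter(denv, rep(1 / w, w), sides = 2)
  env[is.na(env)] <- 0
  env <- as.numeric(env)
  peak <- max(env)
  if (peak <= 0) return(integer(0))
  # impulsiveness gate: QRS trains have sparse high-energy bursts, noise does not
  if (peak < 8 * stats::median(env)) return(integer(0))
  thr <- 0.25 * peak
  refractory <- round(0.2 * fs)
  cand <- which(env > thr)
  if (length(cand) == 0) return(integer(0))
  beats <- integer(0)
  i <- 1L
  while (i <= length(cand)) {
    run_end <- i
    while (run_end < length(cand) && cand[run_end + 1L] - cand[run_end] <= refractory)
      run_end <- run_end + 1L
    seg <- cand[i]:cand[run_end]
    c_env <- seg[which.max(env[seg])]
    # refine on the rectified band-passed signal near the envelope peak
    halfw <- round(0.1 * fs)
    lo <- max(1L, c_env - halfw); hi <- min(n, c_env + halfw)
    p <- (lo:hi)[which.max(abs(filt[lo:hi]))]
    if (length(beats) == 0 || p - beats[length(beats)] > refractory)
      beats <- c(beats, p)
    i <- run_end + 1L
  }
  sort(unique(beats)) - 1L
}
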