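# Frames: half-open, 0-based sample windows into a recording — the unit of
# all pretraining tasks. Common lengths at 250 Hz are 512 (~2 s), 2048
# (~8 s) and 4096 (~16 s).

#' Construct a frame
#' @param recording_index index of the recording within its corpus
#' @param start 0-based first sample of the window
#' @param length window length in samples; the window is `[start, start+length)`
#' @export
frame <- function(recording_index, start, length) {
  if (start < 0) stop("frame start must be >= 0")
  if (length < 1) stop("frame length must be >= 1")
  structure(list(recording_index = as.integer(recording_index),
                 start = as.integer(start), length = as.integer(length)),
            class = "ecg_frame")
}

validate_frame <- function(fr, rec) {
  if (fr$start + fr$length > length(rec$signal))
    stop("frame exceeds recording length")
  invisible(fr)
}

frame_signal <- function(fr, corpus) {
  rec <- corpus$recordings[[fr$recording_index]]
  rec$signal[(fr$start + 1L):(fr$start + fr$length)]
}

#' Sample a random frame from a corpus
#'
#' A patient is chosen uniformly (among patients with at least one segment
#' long enough), then one of that patient's eligible segments uniformly,
#' then the start position uniformly over the valid range. Uses R's global
#' RNG; seed with `set.seed()`.
#'
#' @param corpus an `ecg_corpus`
#' @param frame_length frame length in samples
#' @param patients optional subset of patient ids to sample from
#' @return an [frame()]
#' @export
sample_frame <- function(corpus, frame_length, patients = NULL) {
  idx <- corpus$index
  ok <- idx$n_samples >= frame_length
  if (!is.null(patients)) ok <- ok & idx$patient_id %in% patients
  if (!any(ok)) stop("no recording of at least frame_length samples")
  pats <- unique(idx$patient_id[ok])
  p <- pats[sample.int(length(pats), 1L)]
  segs <- which(ok & idx$patient_id == p)
  ri <- segs[sample.int(length(segs), 1L)]
  max_start <- idx$n_samples[ri] - frame_length
  start <- sample.int(max_start + 1L, 1L) - 1L
  frame(ri, start, frame_length)
}

#' Standardize a signal with corpus-level statistics
#'
#' The mean and standard deviation are corpus-level constants computed once
#' over the entire data set (see [corpus_stats()]), not per frame.
#'
#' @param x numeric vector/matrix/array
#' @param corpus_mean,corpus_sd corpus-level statistics; `corpus_sd` must be > 0
#' @return `(x - corpus_mean) / corpus_sd`
#' @export
standardize <- function(x, corpus_mean, corpus_sd) {
  if (!is.numeric(corpus_sd) || corpus_sd <= 0)
    stop("corpus_sd must be positive (degenerate constant corpus)")
  (x - corpus_mean) / corpus_sd
}

#' Export labeled frames as a CSV-ready manifest
#'
#' Samples `n` frames and labels each with the requested pretraining rule
#' (ground-truth beats for the heart-rate task). Unlabelable beat-task
#' frames (no annotated beat inside) are resampled.
#'
#' @param corpus an `ecg_corpus`
#' @param task one of "beat", "rhythm", "heart_rate"
#' @param frame_length frame length in samples
#' @param n number of frames
#' @param seed integer seed
#' @return data.frame with columns recording_id, start, length, task, label
#' @export
label_frames <- function(corpus, task = c("beat", "rhythm", "heart_rate"),
                         frame_length = 2048L, n = 1000L, seed = 1L) {
  task <- match.arg(task)
  set.seed(seed)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    repeat {
      fr <- sample_frame(corpus, frame_length)
      rec <- corpus$recordings[[fr$recording_index]]
      lab <- switch(task,
        beat = tryCatch(label_beat(fr, rec$beats),
                        ecgtl_unlabelable = function(e) NULL),
        rhythm = label_rhythm(fr, rec$rhythms),
        heart_rate = label_heart_rate(fr, rec))
      if (!is.null(lab)) break
    }
    out[[i]] <- data.frame(recording_id = paste0(rec$patient_id, "_", rec$segment_id),
                           start = fr$start, length = fr$length,
                           task = task, label = lab,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
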