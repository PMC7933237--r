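# Contrastive future-prediction examples: K contiguous context frames, one
# positive future frame at a configurable frame offset, and ns negative
# frames sampled from anywhere in the corpus (any patient, segment and
# position — including the positive's own segment — as long as the window
# does not overlap the positive window).

frames_overlap <- function(a, b) {
  a$recording_index == b$recording_index &&
    a$start < b$start + b$length && b$start < a$start + a$length
}

#' Assemble one contrastive future-prediction example
#'
#' The context is K contiguous equal-length frames from one segment; the
#' positive frame starts `(K + offset) * frame_length` samples after the
#' context start, i.e. `offset` frames lie between context and future.
#' Negatives are drawn uniformly from the corpus, rejecting windows that
#' overlap the positive. Uses R's global RNG.
#'
#' @param corpus an `ecg_corpus`
#' @param context_size K, number of context frames
#' @param frame_length frame length in samples
#' @param offset frames between context end and future start (>= 0)
#' @param ns number of negative samples (>= 1)
#' @param patients optional subset of patient ids
#' @return a `cpc_example`: list with `context` (list of frames), `positive`,
#'   `negatives` (list of frames) and `offset`
#' @export
make_cpc_example <- function(corpus, context_size, frame_length, offset, ns,
                             patients = NULL) {
  if (ns < 1) stop("ns must be >= 1")
  need <- (context_size + offset + 1L) * frame_length
  idx <- corpus$index
  ok <- idx$n_samples >= need
  if (!is.null(patients)) ok <- ok & idx$patient_id %in% patients
  if (!any(ok)) stop("no segment long enough for the requested CPC geometry")
  pats <- unique(idx$patient_id[ok])
  p <- pats[sample.int(length(pats), 1L)]
  segs <- which(ok & idx$patient_id == p)
  ri <- segs[sample.int(length(segs), 1L)]
  max_start <- idx$n_samples[ri] - need
  s <- sample.int(max_start + 1L, 1L) - 1L
  context <- lapply(seq_len(context_size) - 1L, function(i)
    frame(ri, s + i * frame_length, frame_length))
  positive <- frame(ri, s + (context_size + offset) * frame_length, frame_length)
  negatives <- vector("list", ns)
  got <- 0L
  while (got < ns) {
    cand <- sample_frame(corpus, frame_length)
    if (!frames_overlap(cand, positive)) {
      got <- got + 1L
      negatives[[got]] <- cand
    }
  }
  structure(list(context = context, positive = positive, negatives = negatives,
                 offset = as.integer(offset)),
            class = "cpc_example")
}
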