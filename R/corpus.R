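# Synthetic corpora: an upstream continuous-recording corpus (patients x
# segments, beat + rhythm ground truth) and downstream record-level sets
# (short single-lead records with one label each, or 12-lead multi-label
# records).

largest_remainder <- function(n, weights) {
  q <- n * weights / sum(weights)
  counts <- floor(q)
  rem <- q - counts
  short <- n - sum(counts)
  if (short > 0) {
    ord <- order(rem, -counts, decreasing = TRUE)
    counts[ord[seq_len(short)]] <- counts[ord[seq_len(short)]] + 1
  }
  as.integer(counts)
}

# Markov chain of rhythm episodes filling `duration_s` seconds
build_rhythm_plan <- function(duration_s, gp) {
  cls <- character(0); dur <- numeric(0)
  state <- "NSR"
  left <- duration_s
  while (left > 1e-9) {
    d <- min(left, max(5, stats::rexp(1, 1 / gp$episode_mean_s[[state]])))
    cls <- c(cls, state); dur <- c(dur, d)
    left <- left - d
    state <- sample(RHYTHM_CLASSES, 1, prob = gp$transition[state, ])
  }
  data.frame(class = cls, duration_s = dur, stringsAsFactors = FALSE)
}

# subject-level beat morphology (QRS width/amplitude, T/P wave size)
draw_morph <- function() {
  list(qrs_amp = stats::runif(1, 0.85, 1.15),
       qrs_sd = stats::runif(1, 0.013, 0.032),
       t_amp = stats::runif(1, 0.05, 0.40),
       t_sd = stats::runif(1, 0.040, 0.080),
       p_amp = stats::runif(1, 0.06, 0.24))
}

draw_patient_bpm <- function(gp) {
  if (!is.null(gp$nsr_bpm)) return(gp$nsr_bpm)
  if (!is.null(gp$bpm_pool)) return(sample(gp$bpm_pool, 1))
  stats::runif(1, gp$nsr_bpm_range[1], gp$nsr_bpm_range[2])
}

new_corpus <- function(recordings, dir = NULL) {
  index <- data.frame(
    patient_id = vapply(recordings, `[[`, "", "patient_id"),
    segment_id = vapply(recordings, `[[`, "", "segment_id"),
    n_samples = vapply(recordings, function(r) length(r$signal), 0L),
    stringsAsFactors = FALSE)
  structure(list(recordings = recordings, index = index,
                 patients = unique(index$patient_id), dir = dir),
            class = "ecg_corpus")
}

#' @export
print.ecg_corpus <- function(x, ...) {
  cat(sprintf("<ecg_corpus: %d recordings from %d patients, %.1f s total>\n",
              length(x$recordings), length(x$patients),
              sum(x$index$n_samples / vapply(x$recordings, `[[`, 0, "fs"))))
  invisible(x)
}

#' Generate a synthetic upstream corpus of continuous annotated recordings
#'
#' Emulates the shape of a long-term single-lead monitoring corpus: up to 50
#' continuous segments per patient at 250 Hz, with beat annotations and
#' rhythm intervals as exact ground truth. Each patient gets a baseline
#' sinus rate and a Markov chain of rhythm episodes. A splitmix-style child
#' seed per patient makes the corpus reproducible piecewise.
#'
#' @param n_patients number of patients (>= 1)
#' @param segments_per_patient segments per patient (<= 50)
#' @param segment_duration_s duration of each segment in seconds
#' @param gen_params a [gen_params()] object
#' @param seed integer seed driving all randomness
#' @param dir if non-NULL, WFDB files plus `manifest.jsonl` are written there
#' @param fs sampling frequency in Hz
#' @return an `ecg_corpus` (in-memory recordings + index; `$dir` if written)
#' @export
generate_upstream_corpus <- function(n_patients, segments_per_patient = 2L,
                                     segment_duration_s = 60,
                                     gen_params = NULL, seed = 1L,
                                     dir = NULL, fs = 250) {
  if (n_patients < 1) stop("n_patients must be >= 1")
  if (segments_per_patient > 50) stop("at most 50 segments per patient")
  gp <- if (is.null(gen_params)) default_gen_params() else gen_params
  if (!is.null(dir)) {
    if (dir.exists(dir) && file.exists(manifest_path(dir)))
      stop("destination already contains a manifest: ", dir)
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    if (file.access(dirname(manifest_path(dir)), 2) != 0)
      stop("destination not writable: ", dir)
  }
  recordings <- vector("list", n_patients * segments_per_patient)
  k <- 0L
  for (p in seq_len(n_patients)) {
    set.seed(child_seed(seed, p))
    bpm <- draw_patient_bpm(gp)
    gp_p <- gp
    if (isTRUE(gp$per_patient_morph)) gp_p$morph <- draw_morph()
    pid <- sprintf("p%05d", p - 1L)
    for (s in seq_len(segments_per_patient)) {
      set.seed(child_seed(seed, p, s))
      plan <- build_rhythm_plan(segment_duration_s, gp)
      rec <- render_beat_train(plan, gp_p, fs = fs, base_bpm = bpm,
                               patient_id = pid,
                               segment_id = sprintf("s%02d", s - 1L))
      k <- k + 1L
      recordings[[k]] <- rec
      if (!is.null(dir)) write_annotated_recording(rec, dir)
    }
  }
  new_corpus(recordings, dir = dir)
}

#' Load a written corpus back into memory
#' @param dir directory containing WFDB records and `manifest.jsonl`
#' @return an `ecg_corpus`
#' @export
load_corpus <- function(dir) {
  entries <- read_manifest(dir)
  recordings <- lapply(entries, function(e)
    read_annotated_recording(file.path(dir, e$record)))
  new_corpus(recordings, dir = dir)
}

#' Pooled mean and standard deviation of a corpus
#' @param corpus an `ecg_corpus`
#' @return list with `mean` and `sd` computed over all samples of all recordings
#' @export
corpus_stats <- function(corpus) {
  n_tot <- 0; s1 <- 0; s2 <- 0
  for (r in corpus$recordings) {
    n_tot <- n_tot + length(r$signal)
    s1 <- s1 + sum(r$signal)
    s2 <- s2 + sum(r$signal^2)
  }
  m <- s1 / n_tot
  list(mean = m, sd = sqrt(max(s2 / n_tot - m^2, 0)))
}

# --- downstream sets ---------------------------------------------------------

CINC_CLASSES <- c("NORMAL", "AF", "OTHER", "NOISY")
ML12_CLASSES <- c("NSR", "AFIB", "AFLUT", "PVC", "PAC")

downstream_record <- function(record_id, signal, fs, labels, truth = NULL) {
  if (is.null(dim(signal))) signal <- matrix(signal, nrow = 1)
  if (length(labels) == 0) stop("label set must be non-empty")
  structure(list(record_id = record_id, signal = signal, fs = fs,
                 labels = labels, truth = truth),
            class = "downstream_record")
}

render_cinc_record <- function(cls, duration_s, gp, fs = 300) {
  if (cls == "NORMAL") {
    plan <- data.frame(class = "NSR", duration_s = duration_s)
    bpm <- stats::runif(1, 62, 95)
  } else if (cls == "AF") {
    plan <- data.frame(class = "AFIB", duration_s = duration_s)
    bpm <- stats::runif(1, 62, 95)
  } else if (cls == "OTHER") {
    kind <- sample(c("AFLUT", "BRADY", "TACHY"), 1)
    plan <- data.frame(class = if (kind == "AFLUT") "AFLUT" else "NSR",
                       duration_s = duration_s)
    bpm <- switch(kind, AFLUT = 80, BRADY = stats::runif(1, 38, 48),
                  TACHY = stats::runif(1, 115, 140))
  } else {
    plan <- data.frame(class = "NOISE", duration_s = duration_s)
    bpm <- 75
  }
  render_beat_train(plan, gp, fs = fs, base_bpm = bpm)
}

#' Generate a synthetic downstream record set
#'
#' Two profiles: `cinc2017` — single-lead 300 Hz records of 9-60 s, each
#' with exactly one label among NORMAL/AF/OTHER/NOISY, class counts allocated
#' by largest remainder from `class_ratios`; `multilabel12` — 12-lead 500 Hz
#' 10 s records with a non-empty multi-label set over
#' NSR/AFIB/AFLUT/PVC/PAC. AF records are rendered from atrial-fibrillation
#' beat trains (irregular interbeat intervals), so the detection task is
#' learnable by design. Each record keeps its generating ground truth in
#' `$truth`.
#'
#' @param n_records number of records
#' @param profile `"cinc2017"` or `"multilabel12"`
#' @param class_ratios single-label class ratios (must sum to 1); ignored for
#'   the multi-label profile
#' @param seed integer seed
#' @param gen_params a [gen_params()] object
#' @return a list with `records`, `profile` and `classes`
#' @export
generate_downstream_set <- function(n_records,
                                    profile = c("cinc2017", "multilabel12"),
                                    class_ratios = c(NORMAL = 0.6, AF = 0.1,
                                                     OTHER = 0.2, NOISY = 0.1),
                                    seed = 1L, gen_params = NULL) {
  profile <- match.arg(profile)
  if (is.null(gen_params)) gen_params <- default_gen_params()
  records <- vector("list", n_records)
  if (profile == "cinc2017") {
    if (abs(sum(class_ratios) - 1) > 1e-9) stop("class_ratios must sum to 1")
    counts <- largest_remainder(n_records, class_ratios[CINC_CLASSES])
    cls_seq <- rep(CINC_CLASSES, counts)
    set.seed(child_seed(seed, 0L))
    cls_seq <- sample(cls_seq)
    for (i in seq_len(n_records)) {
      set.seed(child_seed(seed, i))
      duration <- stats::runif(1, 9, 60)
      gp_r <- gen_params
      gp_r$morph <- draw_morph()  # every record is a different subject
      rec <- render_cinc_record(cls_seq[i], duration, gp_r, fs = 300)
      records[[i]] <- downstream_record(sprintf("r%05d", i - 1L), rec$signal,
                                        300, cls_seq[i], truth = rec)
    }
    list(records = records, profile = profile, classes = CINC_CLASSES)
  } else {
    for (i in seq_len(n_records)) {
      set.seed(child_seed(seed, i))
      rhythm <- sample(c("NSR", "AFIB", "AFLUT"), 1, prob = c(0.6, 0.25, 0.15))
      gp <- gen_params
      gp$morph <- draw_morph()  # every record is a different subject
      labels <- rhythm
      gp$pvc_rate <- 0; gp$pac_rate <- 0; gp$aberration_rate <- 0
      if (rhythm != "AFLUT") {
        if (stats::runif(1) < 0.4) { gp$pvc_rate <- 0.2; labels <- c(labels, "PVC") }
        if (stats::runif(1) < 0.3) { gp$pac_rate <- 0.15; labels <- c(labels, "PAC") }
      }
      bpm <- stats::runif(1, 55, 105)
      rec <- render_beat_train(data.frame(class = rhythm, duration_s = 10),
                               gp, fs = 500, base_bpm = bpm)
      scales <- stats::runif(12, 0.6, 1.4)
      sig <- outer(scales, rec$signal) +
        matrix(stats::rnorm(12 * length(rec$signal), sd = 0.02), nrow = 12)
      records[[i]] <- downstream_record(sprintf("r%05d", i - 1L), sig, 500,
                                        labels, truth = rec)
    }
    list(records = records, profile = profile, classes = ML12_CLASSES)
  }
}
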