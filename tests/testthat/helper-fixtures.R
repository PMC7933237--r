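# Shared fixtures, built in code. Corpora are memoised per test session.

.fixtures <- new.env(parent = emptyenv())

# jitter-free, abnormality-free params for exact-position assertions
gp_regular <- function(bpm = 60, baseline_noise = 0) {
  gen_params(nsr_bpm = bpm, nsr_jitter_cv = 0, pac_rate = 0, pvc_rate = 0,
             aberration_rate = 0, baseline_noise = baseline_noise)
}

tiny_corpus <- function() {
  if (is.null(.fixtures$tiny)) {
    .fixtures$tiny <- generate_upstream_corpus(
      6, segments_per_patient = 1, segment_duration_s = 40,
      gen_params = gen_params_separable(), seed = 101)
  }
  .fixtures$tiny
}

# one regular recording: 60 BPM NSR, known beat grid
regular_recording <- function(duration_s = 30, bpm = 60, fs = 250) {
  render_beat_train(data.frame(class = "NSR", duration_s = duration_s),
                    gp_regular(bpm), fs = fs)
}

single_recording_corpus <- function(rec) {
  corpus <- generate_upstream_corpus(1, 1, 10, gp_regular(), seed = 1)
  corpus$recordings[[1]] <- rec
  corpus$index$n_samples[1] <- length(rec$signal)
  corpus
}
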