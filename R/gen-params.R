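RHYTHM_CLASSES <- c("NSR", "AFIB", "AFLUT", "NOISE")
BEAT_CLASSES <- c("NORMAL", "PAC", "PVC", "ABERRATION")

#' Parameters of the synthetic ECG generator
#'
#' The generator does not aim for physiological realism; it produces signals
#' whose class structure (interbeat-interval statistics, beat morphology,
#' rhythm episodes) is exactly known, so that every labeler and training
#' stage can be tested against planted ground truth. Atrial fibrillation is
#' made learnable through its defining property — an irregular interbeat
#' interval (high coefficient of variation) and absent P waves — while
#' normal sinus rhythm has a small IBI jitter and atrial flutter a short,
#' very regular IBI. Amplitudes are in arbitrary units (standardization
#' removes scale).
#'
#' @param nsr_bpm baseline sinus rate in BPM; NULL means drawn per patient
#'   from `nsr_bpm_range`
#' @param nsr_bpm_range per-patient uniform range of baseline sinus BPM
#' @param nsr_jitter_cv coefficient of variation of NSR interbeat intervals
#' @param afib_bpm,afib_ibi_cv mean rate and IBI coefficient of variation
#'   during atrial fibrillation (high CV = irregularly irregular)
#' @param aflut_bpm,aflut_jitter_cv rapid regular rate during atrial flutter
#' @param pac_rate,pvc_rate,aberration_rate per-beat probabilities of the
#'   abnormal beat classes
#' @param noise_amp amplitude of band-limited noise in NOISE episodes
#' @param baseline_noise amplitude of measurement noise added everywhere
#' @param transition rhythm episode transition probabilities (4x4 row-
#'   stochastic matrix over NSR/AFIB/AFLUT/NOISE)
#' @param episode_mean_s mean episode duration in seconds per rhythm class
#' @param seed optional generator seed stored with the parameters
#' @return a validated `gen_params` object
#' @export
gen_params <- function(nsr_bpm = NULL, nsr_bpm_range = c(50, 110),
                       nsr_jitter_cv = 0.03,
                       afib_bpm = 110, afib_ibi_cv = 0.25,
                       aflut_bpm = 150, aflut_jitter_cv = 0.01,
                       pac_rate = 0.05, pvc_rate = 0.05, aberration_rate = 0.02,
                       noise_amp = 0.3, baseline_noise = 0.03,
                       transition = NULL,
                       episode_mean_s = c(NSR = 30, AFIB = 20, AFLUT = 15, NOISE = 10),
                       seed = NULL) {
  if (is.null(transition)) {
    transition <- rbind(NSR   = c(0.55, 0.20, 0.10, 0.15),
                        AFIB  = c(0.60, 0.25, 0.05, 0.10),
                        AFLUT = c(0.60, 0.10, 0.20, 0.10),
                        NOISE = c(0.70, 0.10, 0.05, 0.15))
    colnames(transition) <- RHYTHM_CLASSES
  }
  p <- list(nsr_bpm = nsr_bpm, nsr_bpm_range = nsr_bpm_range,
            nsr_jitter_cv = nsr_jitter_cv,
            afib_bpm = afib_bpm, afib_ibi_cv = afib_ibi_cv,
            aflut_bpm = aflut_bpm, aflut_jitter_cv = aflut_jitter_cv,
            pac_rate = pac_rate, pvc_rate = pvc_rate,
            aberration_rate = aberration_rate,
            noise_amp = noise_amp, baseline_noise = baseline_noise,
            transition = transition, episode_mean_s = episode_mean_s,
            morph = list(qrs_amp = 1.0, qrs_sd = 0.02, t_amp = 0.22,
                         t_sd = 0.06, p_amp = 0.15),
            per_patient_morph = FALSE,
            seed = seed)
  rates <- c(pac_rate, pvc_rate, aberration_rate, as.numeric(transition))
  if (any(rates < 0 | rates > 1)) stop("all probabilities must be in [0, 1]")
  if (pac_rate + pvc_rate + aberration_rate > 1)
    stop("abnormal-beat rates must sum to at most 1")
  bpms <- c(nsr_bpm, nsr_bpm_range, afib_bpm, aflut_bpm)
  if (any(bpms <= 0)) stop("rates (BPM) must be positive, so IBI means are positive")
  if (any(abs(rowSums(transition) - 1) > 1e-9))
    stop("transition rows must sum to 1")
  structure(p, class = "gen_params")
}

#' Generator preset with well-separated heart-rate classes
#'
#' Desk-scale training checks use corpora whose classes are separable by
#' construction: patient baseline rates are drawn away from the 60/100 BPM
#' class boundaries (clear bradycardia, normal or tachycardia), rhythm
#' episodes are long, and abnormal-beat rates are moderate. This keeps tiny,
#' briefly-trained models able to learn the planted structure.
#'
#' @param ... overrides passed to [gen_params()]
#' @return a `gen_params` object
#' @export
gen_params_separable <- function(...) {
  transition <- rbind(NSR   = c(0.80, 0.05, 0.05, 0.10),
                      AFIB  = c(0.80, 0.10, 0.00, 0.10),
                      AFLUT = c(0.80, 0.00, 0.10, 0.10),
                      NOISE = c(0.85, 0.05, 0.05, 0.05))
  colnames(transition) <- RHYTHM_CLASSES
  gp <- gen_params(nsr_bpm_range = c(40, 140), nsr_jitter_cv = 0.02,
                   afib_bpm = 130, aflut_bpm = 150,
                   pac_rate = 0.03, pvc_rate = 0.03, aberration_rate = 0.01,
                   transition = transition,
                   episode_mean_s = c(NSR = 90, AFIB = 25, AFLUT = 20, NOISE = 12),
                   ...)
  gp$bpm_pool <- c(42, 48, 54, 70, 78, 86, 94, 112, 124, 136)
  # patients also differ in beat morphology (QRS width/amplitude, T and P
  # wave size), giving contrastive pretraining a patient fingerprint shared
  # by context and future but not by cross-patient negatives
  gp$per_patient_morph <- TRUE
  gp
}

default_gen_params <- function() gen_params()

# Deterministic per-patient / per-segment child seeds (splitmix-style mixing
# of the global seed with stream indices, reduced below 2^31).
child_seed <- function(seed, ...) {
  idx <- c(...)
  x <- as.double(seed %% 2147483647)
  for (i in idx) {
    x <- (x * 69069 + i * 362437 + 1) %% 2147483647
    x <- (x * 18000 + 12345) %% 2147483647
  }
  as.integer(x %% 2147483647)
}
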