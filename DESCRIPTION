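Package: ecgtl
Title: Transfer Learning for ECG Arrhythmia Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Self-supervised and supervised pretraining of 1D residual
    networks on continuous single-lead ECG, and finetuning on short
    record-level arrhythmia classification tasks such as atrial
    fibrillation detection. Includes a synthetic annotated-ECG corpus
    generator with exact ground truth (beat positions and classes,
    rhythm intervals, heart rates), weak-label generation from beat and
    rhythm annotations, a contrastive predictive-coding framework with
    Transformer attention pooling, input-channel adaptation for
    transferring single-lead encoders to 12-lead records, the repeated
    finetuning evaluation protocol, and the challenge evaluation
    metrics (macro F1, class-wise AUC, Fmax, F-beta, G-beta). The
    neural-network core (1D pre-activation residual encoders,
    multi-head self-attention, Adam) is implemented in the package with
    compiled convolution kernels.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    signal,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
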