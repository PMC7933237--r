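# The four pretraining tasks: beat, rhythm and heart-rate classification
# (categorical cross-entropy) and contrastive future prediction. Training
# uses patient-level validation splits, Adam at its default hyperparameters,
# periodic checkpoints and selection of the checkpoint with the highest
# validation accuracy.

PRETRAIN_TASKS <- c("beat", "rhythm", "heart_rate", "future_prediction")

#' Split patients into training and validation sets
#'
#' The split is by patient: no patient contributes to both sets. The
#' validation size is `round(val_fraction * n)`, at least 1.
#'
#' @param patient_ids character vector of patient ids (>= 2)
#' @param val_fraction fraction of patients reserved for validation
#' @param seed optional seed for the draw
#' @return list with `train` and `val` id vectors
#' @export
split_patients <- function(patient_ids, val_fraction = 0.05, seed = NULL) {
  n <- length(patient_ids)
  if (n < 2) stop("need at least 2 patients to split")
  if (val_fraction <= 0 || val_fraction >= 1) stop("val_fraction must be in (0, 1)")
  if (!is.null(seed)) set.seed(seed)
  nval <- max(1L, round(val_fraction * n))
  if (nval >= n) stop("validation fraction leaves no training patients")
  val <- sample(patient_ids, nval)
  list(train = setdiff(patient_ids, val), val = val)
}

#' Total pretraining sampling budget
#'
#' @param n_patients_train number of training patients
#' @param frames_per_patient average frames sampled per patient
#' @return total number of training frames
#' @export
sampling_budget <- function(n_patients_train, frames_per_patient) {
  if (n_patients_train <= 0 || frames_per_patient <= 0)
    stop("inputs must be positive")
  n_patients_train * frames_per_patient
}

#' Report a sampling budget in millions (rounded to 0.1)
#' @param budget total frame count
#' @return budget in millions
#' @export
budget_millions <- function(budget) round(budget / 1e6, 1)

#' Pretraining configuration
#'
#' @param task one of beat, rhythm, heart_rate, future_prediction
#' @param frame_length frame length in samples (presets 512, 2048, 4096)
#' @param max_steps number of optimizer steps (desk-scale budget knob)
#' @param batch_size examples per step
#' @param context_size,ns,offset contrastive-task geometry (K context
#'   frames, ns negatives, offset frames between context and future)
#' @param frames_per_patient average frames per patient (reporting)
#' @param val_patient_fraction fraction of patients held out by patient
#' @param checkpoint_interval_steps validation/checkpoint period
#' @param n_val validation examples drawn once from validation patients
#' @param beat_source beat source for heart-rate labels
#' @param lr Adam learning rate (Adam defaults otherwise)
#' @param seed integer seed for the whole run
#' @export
pretrain_config <- function(task, frame_length = 2048L, max_steps = 1000L,
                            batch_size = 32L, context_size = 8L, ns = 4L,
                            offset = 2L, frames_per_patient = 4096L,
                            val_patient_fraction = 0.05,
                            checkpoint_interval_steps = 2000L, n_val = 256L,
                            beat_source = "ground_truth", lr = 1e-3, seed = 1L) {
  task <- match.arg(task, PRETRAIN_TASKS)
  if (val_patient_fraction <= 0 || val_patient_fraction >= 1)
    stop("val_patient_fraction must be in (0, 1)")
  if (checkpoint_interval_steps < 1) stop("checkpoint_interval_steps must be >= 1")
  list(task = task, frame_length = as.integer(frame_length),
       max_steps = as.integer(max_steps), batch_size = as.integer(batch_size),
       context_size = as.integer(context_size), ns = as.integer(ns),
       offset = as.integer(offset),
       frames_per_patient = as.integer(frames_per_patient),
       val_patient_fraction = val_patient_fraction,
       checkpoint_interval_steps = as.integer(checkpoint_interval_steps),
       n_val = as.integer(n_val), beat_source = beat_source, lr = lr,
       seed = as.integer(seed))
}

task_classes <- function(task) {
  switch(task, beat = BEAT_CLASSES, rhythm = RHYTHM_CLASSES,
         heart_rate = HR_CLASSES,
         stop("task has no class set: ", task))
}

# Sample a labeled classification batch; beat-task frames with no annotated
# beat are resampled.
sample_labeled_batch <- function(corpus, task, frame_length, patients, stats,
                                 n, beat_source = "ground_truth") {
  classes <- task_classes(task)
  x <- array(0, c(1L, frame_length, n))
  y <- integer(n)
  pids <- character(n)
  for (i in seq_len(n)) {
    repeat {
      fr <- sample_frame(corpus, frame_length, patients = patients)
      rec <- corpus$recordings[[fr$recording_index]]
      lab <- switch(task,
        beat = tryCatch(label_beat(fr, rec$beats),
                        ecgtl_unlabelable = function(e) NULL),
        rhythm = label_rhythm(fr, rec$rhythms),
        heart_rate = label_heart_rate(fr, rec, beat_source = beat_source))
      if (!is.null(lab)) break
    }
    x[1, , i] <- standardize(frame_signal(fr, corpus), stats$mean, stats$sd)
    y[i] <- match(lab, classes)
    pids[i] <- rec$patient_id
  }
  list(x = x, y = y, patient_ids = pids)
}

# --- contrastive model -------------------------------------------------------

build_cpc_model <- function(spec, ap_spec = NULL) {
  enc <- build_encoder(spec)
  if (is.null(ap_spec)) ap_spec <- attention_pool_spec(d_model = enc$out_dim)
  if (ap_spec$d_model != enc$out_dim)
    stop("attention-pool d_model must equal the encoder feature size")
  m <- new.env(parent = emptyenv())
  m$encoder <- enc
  m$pool <- build_attention_pool(ap_spec)
  m$spec <- spec
  m$ap_spec <- ap_spec
  class(m) <- "ecgtl_cpc"
  m
}

cpc_model_layers <- function(m) c(encoder_layers(m$encoder), attention_pool_layers(m$pool))

# Assemble a CPC batch: per example K standardized context frames followed by
# the ns+1 candidate frames with the positive at a random position.
assemble_cpc_batch <- function(corpus, cfg, patients, stats, n) {
  kk <- cfg$context_size; ns <- cfg$ns; L <- cfg$frame_length
  per <- kk + ns + 1L
  x <- array(0, c(1L, L, n * per))
  target <- integer(n)
  pids <- character(n)
  for (i in seq_len(n)) {
    ex <- make_cpc_example(corpus, kk, L, cfg$offset, ns, patients = patients)
    pos_at <- sample.int(ns + 1L, 1L)
    target[i] <- pos_at
    cands <- append(ex$negatives, list(ex$positive), after = pos_at - 1L)
    frames <- c(ex$context, cands)
    base <- (i - 1L) * per
    for (j in seq_along(frames))
      x[1, , base + j] <- standardize(frame_signal(frames[[j]], corpus),
                                      stats$mean, stats$sd)
    pids[i] <- corpus$recordings[[ex$positive$recording_index]]$patient_id
  }
  list(x = x, target = target, patient_ids = pids, n = n, per = per)
}

cpc_forward <- function(m, batch, cfg, training = TRUE) {
  kk <- cfg$context_size; ns <- cfg$ns
  d <- m$encoder$out_dim
  feat <- encoder_forward(m$encoder, batch$x, training)
  n <- batch$n; per <- batch$per
  ctx <- array(0, c(d, kk, n))
  cand <- array(0, c(d, ns + 1L, n))
  for (i in seq_len(n)) {
    base <- (i - 1L) * per
    ctx[, , i] <- feat[, base + seq_len(kk)]
    cand[, , i] <- feat[, base + kk + seq_len(ns + 1L)]
  }
  cvec <- attention_pool(m$pool, ctx)
  z <- matrix(0, ns + 1L, n)
  for (i in seq_len(n)) z[, i] <- as.numeric(t(cand[, , i]) %*% cvec[, i])
  ce <- cross_entropy(z, batch$target)
  acc <- mean(apply(z, 2, which.max) == batch$target)
  list(loss = ce$loss, acc = acc, dlogits = ce$dlogits, cvec = cvec,
       cand = cand, feat_dims = dim(feat))
}

cpc_backward <- function(m, fw, batch, cfg) {
  kk <- cfg$context_size; ns <- cfg$ns
  d <- m$encoder$out_dim
  n <- batch$n; per <- batch$per
  dz <- fw$dlogits
  dc <- matrix(0, d, n)
  dcand <- array(0, c(d, ns + 1L, n))
  for (i in seq_len(n)) {
    dc[, i] <- fw$cand[, , i] %*% dz[, i]
    dcand[, , i] <- outer(fw$cvec[, i], dz[, i])
  }
  dctx <- attention_pool_backward(m$pool, dc)
  dfeat <- matrix(0, d, n * per)
  for (i in seq_len(n)) {
    base <- (i - 1L) * per
    dfeat[, base + seq_len(kk)] <- dctx[, , i]
    dfeat[, base + kk + seq_len(ns + 1L)] <- dcand[, , i]
  }
  encoder_backward(m$encoder, dfeat)
  invisible(NULL)
}

# --- the pretraining loop ----------------------------------------------------

#' Run a pretraining task over a corpus
#'
#' Minimizes categorical cross-entropy with Adam (default hyperparameters)
#' over frames sampled from training patients only; evaluates accuracy on a
#' fixed validation set drawn from held-out patients at every checkpoint;
#' returns the model reverted to the checkpoint with the highest validation
#' accuracy (ties resolve to the earliest step). For the contrastive task
#' the validation metric is positive-identification accuracy.
#'
#' @param corpus an `ecg_corpus` (or a directory to load)
#' @param spec a [model_spec()]
#' @param config a [pretrain_config()]
#' @param log_file optional JSON-lines training log path
#' @return list with `model`, `history` (step, train_loss, val_accuracy),
#'   `best_step`, `split`, `provenance` (training-batch patient ids),
#'   `stats`, `config`
#' @export
run_pretraining <- function(corpus, spec, config, log_file = NULL) {
  if (is.character(corpus)) corpus <- load_corpus(corpus)
  if (length(corpus$recordings) == 0) stop("corpus is empty")
  cfg <- config
  is_cpc <- cfg$task == "future_prediction"
  if (is_cpc) {
    need <- (cfg$context_size + cfg$offset + 1L) * cfg$frame_length
    if (max(corpus$index$n_samples) < need)
      stop("CPC geometry impossible: no segment has ", need, " samples")
  } else {
    if (max(corpus$index$n_samples) < cfg$frame_length)
      stop("no recording of at least frame_length samples")
  }
  set.seed(cfg$seed)
  split <- split_patients(corpus$patients, cfg$val_patient_fraction)
  stats <- corpus_stats(corpus)

  if (is_cpc) {
    model <- build_cpc_model(spec)
    layers <- cpc_model_layers(model)
    val_batch <- assemble_cpc_batch(corpus, cfg, split$val, stats, cfg$n_val)
    get_state <- function() list(enc = encoder_state(model$encoder),
                                 pool = lapply(attention_pool_layers(model$pool),
                                               layer_state))
    load_state <- function(st) {
      encoder_load_state(model$encoder, st$enc)
      pls <- attention_pool_layers(model$pool)
      for (i in seq_along(pls)) layer_load_state(pls[[i]], st$pool[[i]])
    }
    eval_acc <- function() cpc_forward(model, val_batch, cfg, training = FALSE)$acc
  } else {
    classes <- task_classes(cfg$task)
    sp <- spec; sp$n_classes <- length(classes)
    model <- build_classifier(sp)
    layers <- model_layers(model)
    val_batch <- sample_labeled_batch(corpus, cfg$task, cfg$frame_length,
                                      split$val, stats, cfg$n_val,
                                      cfg$beat_source)
    get_state <- function() model_state(model)
    load_state <- function(st) model_load_state(model, st)
    eval_acc <- function() {
      p <- classify(model, val_batch$x)
      mean(apply(p, 2, which.max) == val_batch$y)
    }
  }

  opt <- adam_new(layers, lr = cfg$lr)
  history <- data.frame(step = integer(0), train_loss = numeric(0),
                        val_accuracy = numeric(0))
  best <- list(acc = -Inf, step = NA_integer_, state = NULL)
  provenance <- character(0)
  loss_acc <- 0; loss_n <- 0L
  log_con <- if (!is.null(log_file)) file(log_file, "w") else NULL
  on.exit(if (!is.null(log_con)) close(log_con))

  for (step in seq_len(cfg$max_steps)) {
    if (is_cpc) {
      batch <- assemble_cpc_batch(corpus, cfg, split$train, stats, cfg$batch_size)
      fw <- cpc_forward(model, batch, cfg, training = TRUE)
      zero_grad(layers)
      cpc_backward(model, fw, batch, cfg)
      loss <- fw$loss
    } else {
      batch <- sample_labeled_batch(corpus, cfg$task, cfg$frame_length,
                                    split$train, stats, cfg$batch_size,
                                    cfg$beat_source)
      z <- model_logits(model, batch$x, training = TRUE)
      ce <- cross_entropy(z, batch$y)
      zero_grad(layers)
      dfeat <- layer_backward(model$head, ce$dlogits)
      encoder_backward(model$encoder, dfeat)
      loss <- ce$loss
    }
    adam_step(opt)
    provenance <- union(provenance, batch$patient_ids)
    loss_acc <- loss_acc + loss; loss_n <- loss_n + 1L

    if (step %% cfg$checkpoint_interval_steps == 0L || step == cfg$max_steps) {
      acc <- eval_acc()
      history <- rbind(history, data.frame(step = step,
                                           train_loss = loss_acc / loss_n,
                                           val_accuracy = acc))
      loss_acc <- 0; loss_n <- 0L
      if (acc > best$acc) best <- list(acc = acc, step = step, state = get_state())
      if (!is.null(log_con))
        writeLines(jsonlite::toJSON(list(step = step, loss = loss,
                                         val_accuracy = acc),
                                    auto_unbox = TRUE, digits = NA), log_con)
    }
  }
  load_state(best$state)
  list(model = model, history = history, best_step = best$step,
       best_val_accuracy = best$acc, split = split, provenance = provenance,
       stats = stats, config = cfg)
}
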