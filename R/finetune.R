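# Downstream transfer: preprocessing (dataset-level standardization,
# polyphase resampling to the pretraining rate, zero-padding to a uniform
# length), head replacement, end-to-end training with early stopping on
# training accuracy and checkpointing on a validation criterion, and the
# repeated-evaluation protocol (fixed test set, resampled train/validation).

#' Polyphase rational resampling
#'
#' Upsamples by the rational factor p/q = fs_out/fs_in (zero stuffing),
#' applies a zero-phase FIR low-pass at the tighter of the two Nyquist
#' limits (windowed-sinc design, delay compensated), and decimates. Content
#' band-limited below `min(fs_in, fs_out)/2` is preserved.
#'
#' @param x numeric vector
#' @param fs_in,fs_out sampling frequencies in Hz (> 0)
#' @return resampled signal of length `round(length(x) * fs_out / fs_in)`
#' @export
resample_signal <- function(x, fs_in, fs_out) {
  if (fs_in <= 0 || fs_out <= 0) stop("sampling rates must be positive")
  if (fs_in == fs_out) return(x)
  g <- gcd_int(round(fs_out), round(fs_in))
  p <- round(fs_out) / g; q <- round(fs_in) / g
  n <- length(x)
  up <- numeric(n * p)
  up[seq(1, by = p, length.out = n)] <- x * p
  taps <- 20L * max(p, q) + 1L   # odd length, exactly centered
  h <- signal::fir1(taps - 1L, 1 / max(p, q))
  half <- (taps - 1L) %/% 2L
  padded <- c(numeric(half), up, numeric(half))
  filt <- stats::filter(padded, h, method = "convolution", sides = 2)
  filt <- as.numeric(filt[(half + 1L):(half + n * p)])
  y <- filt[seq(1, by = q, length.out = ceiling(n * p / q))]
  n_out <- round(n * fs_out / fs_in)
  if (length(y) >= n_out) y[seq_len(n_out)] else c(y, numeric(n_out - length(y)))
}

gcd_int <- function(a, b) if (b == 0) a else gcd_int(b, a %% b)

#' Finetuning configuration
#'
#' @param max_epochs training epoch cap (default 200)
#' @param early_stop_patience epochs without a strict training-accuracy
#'   improvement before stopping (default 50)
#' @param checkpoint_criterion `"val_macro_f1"` (single-label) or
#'   `"val_loss"` (multi-label)
#' @param target_fs target sampling frequency in Hz (default 250, the
#'   upstream rate)
#' @param target_len_s uniform signal length in seconds after zero-padding
#' @param n_runs repetitions of the finetuning protocol (default 10)
#' @param split train/val/test fractions (default .75/.05/.20; must sum to 1)
#' @param batch_size minibatch size
#' @param lr Adam learning rate
#' @param seed integer seed
#' @export
finetune_config <- function(max_epochs = 200L, early_stop_patience = 50L,
                            checkpoint_criterion = c("val_macro_f1", "val_loss"),
                            target_fs = 250, target_len_s = 60, n_runs = 10L,
                            split = c(train = 0.75, val = 0.05, test = 0.20),
                            batch_size = 16L, lr = 1e-3, seed = 1L) {
  checkpoint_criterion <- match.arg(checkpoint_criterion)
  if (abs(sum(split) - 1) > 1e-9) stop("split fractions must sum to 1")
  if (early_stop_patience >= max_epochs) stop("patience must be below max_epochs")
  list(max_epochs = as.integer(max_epochs),
       early_stop_patience = as.integer(early_stop_patience),
       checkpoint_criterion = checkpoint_criterion,
       target_fs = target_fs, target_len_s = target_len_s,
       n_runs = as.integer(n_runs), split = split,
       batch_size = as.integer(batch_size), lr = lr, seed = as.integer(seed))
}

#' Preprocess a downstream record into a model-ready matrix
#'
#' Standardizes with dataset-level statistics, resamples each lead to
#' `target_fs`, and right-pads with zeros to `target_len_s * target_fs`
#' samples (records longer than the target are tail-truncated).
#'
#' @param record a downstream record
#' @param config a [finetune_config()]
#' @param stats dataset-level `list(mean, sd)`
#' @return matrix (n_leads, target_len_s * target_fs)
#' @export
preprocess_downstream <- function(record, config, stats) {
  n_out <- round(config$target_len_s * config$target_fs)
  sig <- standardize(record$signal, stats$mean, stats$sd)
  out <- matrix(0, nrow(sig), n_out)
  for (ld in seq_len(nrow(sig))) {
    y <- resample_signal(sig[ld, ], record$fs, config$target_fs)
    m <- min(length(y), n_out)
    out[ld, seq_len(m)] <- y[seq_len(m)]
  }
  out
}

downstream_set_stats <- function(dset) {
  n_tot <- 0; s1 <- 0; s2 <- 0
  for (r in dset$records) {
    n_tot <- n_tot + length(r$signal)
    s1 <- s1 + sum(r$signal)
    s2 <- s2 + sum(r$signal^2)
  }
  m <- s1 / n_tot
  list(mean = m, sd = sqrt(max(s2 / n_tot - m^2, 0)))
}

#' Prepare a downstream set for training
#'
#' Computes dataset-level standardization statistics (over the entire set,
#' as the transfer protocol specifies — the train/test leakage this implies
#' is deliberate and documented), preprocesses every record, and encodes
#' labels (integer classes for the single-label profile, a 0/1 matrix for
#' the multi-label profile).
#'
#' @param dset result of [generate_downstream_set()]
#' @param config a [finetune_config()]
#' @return list with `x` (leads, length, n), `labels`, `y`, `classes`,
#'   `profile`, `stats`
#' @export
prepare_downstream <- function(dset, config) {
  stats <- downstream_set_stats(dset)
  n <- length(dset$records)
  n_len <- round(config$target_len_s * config$target_fs)
  leads <- nrow(dset$records[[1]]$signal)
  x <- array(0, c(leads, n_len, n))
  for (i in seq_len(n)) x[, , i] <- preprocess_downstream(dset$records[[i]], config, stats)
  if (dset$profile == "cinc2017") {
    labels <- vapply(dset$records, function(r) r$labels[1], "")
    y <- match(labels, dset$classes)
    list(x = x, labels = labels, y = y, classes = dset$classes,
         profile = dset$profile, stats = stats)
  } else {
    y <- t(vapply(dset$records, function(r) as.integer(dset$classes %in% r$labels),
                  integer(length(dset$classes))))
    list(x = x, labels = lapply(dset$records, `[[`, "labels"), y = y,
         classes = dset$classes, profile = dset$profile, stats = stats)
  }
}

#' Stratified split by label
#'
#' Allocates each class across the splits proportionally with
#' largest-remainder rounding (so each split's class count is within 1
#' record of the exact proportion); splits are disjoint and exhaustive.
#'
#' @param labels vector of class labels
#' @param fractions named fractions summing to 1 (e.g. train/val/test)
#' @param seed integer seed for the shuffle
#' @return list of index vectors named after `fractions`
#' @export
stratified_split <- function(labels, fractions, seed = 1L) {
  if (abs(sum(fractions) - 1) > 1e-9) stop("fractions must sum to 1")
  set.seed(seed)
  out <- lapply(fractions, function(f) integer(0))
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    n_c <- length(idx)
    q <- n_c * fractions
    base <- floor(q)
    left <- n_c - sum(base)
    if (left > 0) {
      ord <- order(q - base, -base, decreasing = TRUE)
      base[ord[seq_len(left)]] <- base[ord[seq_len(left)]] + 1
    }
    if (any(fractions > 0 & base == 0))
      stop("class '", cl, "' is too small to appear in every non-empty split")
    off <- 0L
    for (s in seq_along(fractions)) {
      out[[s]] <- c(out[[s]], idx[off + seq_len(base[s])])
      off <- off + base[s]
    }
  }
  lapply(out, sort)
}

#' Fold-based split (alternative split mode for multi-label corpora)
#'
#' Records are assigned to `n_folds` folds round-robin after a seeded
#' shuffle; train/validation/test are unions of whole folds (mirroring
#' recommended fold-based benchmark splits).
#'
#' @param n number of records
#' @param n_folds number of folds (default 10)
#' @param train_folds,val_folds,test_folds fold ids per split
#' @param seed integer seed for the shuffle
#' @return list of index vectors `train`, `val`, `test`
#' @export
fold_split <- function(n, n_folds = 10L, train_folds = 1:8, val_folds = 9L,
                       test_folds = 10L, seed = 1L) {
  set.seed(seed)
  fold <- rep_len(seq_len(n_folds), n)[sample.int(n)]
  list(train = sort(which(fold %in% train_folds)),
       val = sort(which(fold %in% val_folds)),
       test = sort(which(fold %in% test_folds)))
}

# --- finetuning loop ---------------------------------------------------------

copy_encoder <- function(enc) {
  e2 <- build_encoder(enc$spec)
  encoder_load_state(e2, encoder_state(enc))
  e2
}

# Build a downstream classifier: full 4-stage encoder at the data's lead
# count, initialized from a pretrained encoder when given (adapting the
# first layer to the lead count and freshly initializing any stage the
# pretrained encoder lacks), with a freshly initialized head.
init_downstream_model <- function(init, spec, n_leads, n_classes, activation) {
  sp <- spec
  sp$in_channels <- as.integer(n_leads)
  sp$stages_used <- 4L
  sp$n_classes <- as.integer(n_classes)
  enc <- build_encoder(sp)
  if (!is.null(init)) {
    src <- if (inherits(init, "ecgtl_classifier")) init$encoder
           else if (inherits(init, "ecgtl_cpc")) init$encoder else init
    src <- copy_encoder(src)
    if (src$spec$in_channels == 1L && n_leads > 1L)
      adapt_input_channels(src, n_leads)
    if (src$spec$in_channels != n_leads)
      stop("pretrained encoder lead count incompatible with data")
    init_encoder_from(enc, src)
  }
  m <- replace_head(enc, n_classes, activation)
  m
}

predict_scores <- function(model, x, idx = NULL, batch = 32L) {
  if (is.null(idx)) idx <- seq_len(dim(x)[3])
  out <- matrix(0, model$spec$n_classes, length(idx))
  for (b in split(seq_along(idx), ceiling(seq_along(idx) / batch))) {
    out[, b] <- classify(model, x[, , idx[b], drop = FALSE])
  }
  out
}

#' Finetune a model on a downstream data set
#'
#' End-to-end training (no weights are frozen) with Adam; training stops
#' early when training accuracy has not strictly improved for
#' `early_stop_patience` epochs; the returned model carries the weights of
#' the epoch with the best checkpoint criterion (highest validation macro
#' F1 for single-label, lowest validation loss for multi-label).
#'
#' @param init a pretrained encoder/model, or NULL for random initialization
#' @param data result of [prepare_downstream()]
#' @param train_idx,val_idx disjoint index sets into the data
#' @param spec a [model_spec()]
#' @param config a [finetune_config()]
#' @return list with `model` and `history` (per-epoch data.frame)
#' @export
run_finetune <- function(init, data, train_idx, val_idx, spec, config) {
  if (length(train_idx) == 0 || length(val_idx) == 0) stop("empty split")
  if (length(intersect(train_idx, val_idx)) > 0) stop("splits must be disjoint")
  multilabel <- data$profile != "cinc2017"
  n_classes <- length(data$classes)
  model <- init_downstream_model(init, spec, dim(data$x)[1], n_classes,
                                 if (multilabel) "sigmoid" else "softmax")
  layers <- model_layers(model)
  opt <- adam_new(layers, lr = config$lr)
  best <- list(score = -Inf, epoch = NA_integer_, state = NULL)
  best_train_acc <- -Inf
  stale <- 0L
  history <- NULL
  for (epoch in seq_len(config$max_epochs)) {
    ord <- sample(train_idx)
    n_correct <- 0; n_seen <- 0; loss_sum <- 0; nb <- 0L
    for (b in split(ord, ceiling(seq_along(ord) / config$batch_size))) {
      xb <- data$x[, , b, drop = FALSE]
      z <- model_logits(model, xb, training = TRUE)
      if (multilabel) {
        yb <- t(data$y[b, , drop = FALSE])
        ce <- binary_cross_entropy(z, yb)
        n_correct <- n_correct + sum((ce$prob > 0.5) == (yb == 1))
        n_seen <- n_seen + length(yb)
      } else {
        yb <- data$y[b]
        ce <- cross_entropy(z, yb)
        n_correct <- n_correct + sum(apply(z, 2, which.max) == yb)
        n_seen <- n_seen + length(yb)
      }
      zero_grad(layers)
      dfeat <- layer_backward(model$head, ce$dlogits)
      encoder_backward(model$encoder, dfeat)
      adam_step(opt)
      loss_sum <- loss_sum + ce$loss; nb <- nb + 1L
    }
    train_acc <- n_correct / n_seen
    sc <- predict_scores(model, data$x, val_idx, config$batch_size)
    if (multilabel) {
      yv <- t(data$y[val_idx, , drop = FALSE])
      val_loss <- -mean(yv * log(pmax(sc, 1e-12)) +
                        (1 - yv) * log(pmax(1 - sc, 1e-12)))
      score <- -val_loss
      val_metric <- val_loss
    } else {
      pred <- data$classes[apply(sc, 2, which.max)]
      val_metric <- macro_f1(data$labels[val_idx], pred, data$classes)$macro_f1
      score <- val_metric
    }
    history <- rbind(history, data.frame(epoch = epoch,
                                         train_loss = loss_sum / nb,
                                         train_accuracy = train_acc,
                                         val_metric = val_metric))
    if (score > best$score)
      best <- list(score = score, epoch = epoch, state = model_state(model))
    if (train_acc > best_train_acc) {
      best_train_acc <- train_acc
      stale <- 0L
    } else {
      stale <- stale + 1L
      if (stale >= config$early_stop_patience) break
    }
  }
  model_load_state(model, best$state)
  list(model = model, history = history, best_epoch = best$epoch,
       best_score = best$score)
}

# Test-set metrics for one finetuned model
evaluate_on_test <- function(model, data, test_idx, train_idx, config) {
  sc <- predict_scores(model, data$x, test_idx, config$batch_size)
  if (data$profile == "cinc2017") {
    pred <- data$classes[apply(sc, 2, which.max)]
    mf <- macro_f1(data$labels[test_idx], pred, data$classes)
    out <- c(macro_f1 = mf$macro_f1, stats::setNames(mf$per_class,
             paste0("f1_", tolower(data$classes))))
  } else {
    y_test <- data$y[test_idx, , drop = FALSE]
    s_test <- t(sc)
    s_train <- t(predict_scores(model, data$x, train_idx, config$batch_size))
    y_train <- data$y[train_idx, , drop = FALSE]
    thr_fb <- threshold_search(y_train, s_train,
                               function(y, p) f_beta_g_beta(y, p)$f_beta)
    thr_gb <- threshold_search(y_train, s_train,
                               function(y, p) f_beta_g_beta(y, p)$g_beta)
    out <- c(auc = mean_classwise_auc(y_test, s_test),
             f_max = f_max(y_test, s_test),
             f_beta = f_beta_g_beta(y_test, (s_test >= thr_fb) * 1)$f_beta,
             g_beta = f_beta_g_beta(y_test, (s_test >= thr_gb) * 1)$g_beta)
  }
  out
}

#' Repeated finetuning evaluation
#'
#' Holds out a fixed test set (20% by default, stratified for the
#' single-label profile), then repeats the finetuning procedure `n_runs`
#' times, each time drawing fresh train and validation sets from the
#' remaining pool, and reports per-run test metrics with their mean and
#' standard deviation.
#'
#' @param init pretrained encoder/model or NULL for random initialization
#' @param data result of [prepare_downstream()]
#' @param spec a [model_spec()]
#' @param config a [finetune_config()]
#' @return an `eval_report`: list with `per_run` (data.frame), `mean`, `sd`,
#'   `test_idx` and `config`
#' @export
repeated_evaluation <- function(init, data, spec, config) {
  if (config$n_runs < 1) stop("n_runs must be >= 1")
  n <- dim(data$x)[3]
  pool_frac <- 1 - config$split[["test"]]
  strat_labels <- if (data$profile == "cinc2017") data$labels
                  else vapply(data$labels, `[[`, "", 1)  # primary rhythm label
  outer <- stratified_split(strat_labels, c(pool = pool_frac,
                                            test = config$split[["test"]]),
                            seed = config$seed)
  pool_idx <- outer$pool; test_idx <- outer$test
  runs <- vector("list", config$n_runs)
  for (r in seq_len(config$n_runs)) {
    run_seed <- child_seed(config$seed, r)
    inner <- stratified_split(strat_labels[pool_idx],
                              c(train = config$split[["train"]] / pool_frac,
                                val = config$split[["val"]] / pool_frac),
                              seed = run_seed)
    train_idx <- pool_idx[inner$train]
    val_idx <- pool_idx[inner$val]
    set.seed(run_seed)
    ft <- run_finetune(init, data, train_idx, val_idx, spec, config)
    runs[[r]] <- c(run = r, evaluate_on_test(ft$model, data, test_idx,
                                             train_idx, config))
  }
  per_run <- as.data.frame(do.call(rbind, runs))
  metrics <- setdiff(names(per_run), "run")
  structure(list(per_run = per_run,
                 mean = colMeans(per_run[, metrics, drop = FALSE]),
                 sd = apply(per_run[, metrics, drop = FALSE], 2, stats::sd),
                 test_idx = test_idx, config = config),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report: %d runs>\n", nrow(x$per_run)))
  for (m in names(x$mean))
    cat(sprintf("  %-10s %.3f (+/- %.3f)\n", m, x$mean[[m]], x$sd[[m]]))
  invisible(x)
}
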