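test_that("rational resampling preserves length and band-limited content", {
  x <- sin(2 * pi * 10 * (0:17999) / 300)
  y <- resample_signal(x, 300, 250)
  expect_length(y, 15000)
  expect_identical(resample_signal(x, 300, 300), x)
  # compare against the analytically resampled sinusoid away from the edges
  t <- (0:14999) / 250
  ref <- sin(2 * pi * 10 * t)
  core <- 200:14800
  expect_lt(max(abs(y[core] - ref[core])), 1e-2)
  expect_error(resample_signal(x, 0, 250), "positive")
})

test_that("downstream preprocessing standardizes, resamples and zero-pads", {
  set.seed(1)
  dset <- generate_downstream_set(6, "cinc2017",
                                  class_ratios = c(NORMAL = 1, AF = 0,
                                                   OTHER = 0, NOISY = 0),
                                  seed = 11)
  cfg <- finetune_config(seed = 1)
  stats <- ecgtl:::downstream_set_stats(dset)
  rec <- dset$records[[1]]
  out <- preprocess_downstream(rec, cfg, stats)
  expect_equal(dim(out), c(1, 15000))
  n_res <- round(ncol(rec$signal) * 250 / 300)
  if (n_res < 15000) expect_true(all(out[1, (n_res + 1):15000] == 0))
  # a 9 s record keeps only 9 * 250 samples of content
  nine <- rec
  nine$signal <- rec$signal[, 1:(9 * 300), drop = FALSE]
  out9 <- preprocess_downstream(nine, cfg, stats)
  expect_true(all(out9[1, (9 * 250 + 1):15000] == 0))
  expect_gt(sum(abs(out9[1, 1:(9 * 250)])), 0)
  # a 128 Hz target keeps the same relative input length: 60 s * 128
  cfg128 <- finetune_config(target_fs = 128, seed = 1)
  expect_equal(dim(preprocess_downstream(rec, cfg128, stats)), c(1, 7680))
})

test_that("stratified splits are proportional within one record per class", {
  labels <- rep(c("A", "B", "C", "D"), c(60, 10, 20, 10))
  sp <- stratified_split(labels, c(train = .75, val = .05, test = .20), seed = 3)
  # allocation is per class (largest remainder), so each split total is
  # within one record per class of the exact proportion
  expect_lte(abs(length(sp$train) - 75), 3)
  expect_lte(abs(length(sp$val) - 5), 3)
  expect_lte(abs(length(sp$test) - 20), 3)
  expect_setequal(unlist(sp), seq_along(labels))
  expect_length(intersect(sp$train, sp$test), 0)
  for (cl in unique(labels)) {
    n_c <- sum(labels == cl)
    for (s in names(sp)) {
      frac <- c(train = .75, val = .05, test = .20)[[s]]
      expect_lt(abs(sum(labels[sp[[s]]] == cl) - n_c * frac), 1)
    }
  }
  expect_error(stratified_split(rep(c("A", "B"), c(98, 2)),
                                c(train = .75, val = .05, test = .20)),
               "too small")
  one <- stratified_split(rep("A", 100), c(train = .75, val = .05, test = .20),
                          seed = 1)
  expect_equal(lengths(one), c(train = 75L, val = 5L, test = 20L))
})

test_that("fold-based splitting partitions records into whole folds", {
  sp <- fold_split(103, seed = 5)
  expect_setequal(unlist(sp), 1:103)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_equal(length(sp$train) + length(sp$val) + length(sp$test), 103)
  expect_gt(length(sp$train), length(sp$test))
})

test_that("finetuning stops early, checkpoints the best epoch and reproduces it", {
  set.seed(2)
  dset <- generate_downstream_set(40, "cinc2017",
                                  class_ratios = c(NORMAL = .5, AF = .5,
                                                   OTHER = 0, NOISY = 0),
                                  seed = 13)
  cfg <- finetune_config(max_epochs = 6, early_stop_patience = 2,
                         batch_size = 8, target_len_s = 20, seed = 2)
  data <- prepare_downstream(dset, cfg)
  sp <- stratified_split(data$labels, c(train = .6, val = .4), seed = 2)
  ft <- run_finetune(NULL, data, sp$train, sp$val, model_spec(18, 0.0625), cfg)
  expect_lte(nrow(ft$history), 6)
  expect_equal(max(ft$history$val_metric), ft$best_score)
  # reverted weights reproduce the recorded best validation metric
  sc <- ecgtl:::predict_scores(ft$model, data$x, sp$val, 8)
  pred <- data$classes[apply(sc, 2, which.max)]
  again <- macro_f1(data$labels[sp$val], pred, data$classes)$macro_f1
  expect_equal(again, ft$best_score, tolerance = 1e-12)
  expect_error(run_finetune(NULL, data, integer(0), sp$val,
                            model_spec(18, 0.0625), cfg), "empty")
  expect_error(run_finetune(NULL, data, sp$train, sp$train[1],
                            model_spec(18, 0.0625), cfg), "disjoint")
})

test_that("repeated evaluation keeps one fixed test set and aggregates runs", {
  set.seed(3)
  dset <- generate_downstream_set(40, "cinc2017",
                                  class_ratios = c(NORMAL = .5, AF = .5,
                                                   OTHER = 0, NOISY = 0),
                                  seed = 17)
  cfg <- finetune_config(max_epochs = 2, early_stop_patience = 1, n_runs = 3,
                         batch_size = 8, target_len_s = 20, seed = 5)
  data <- prepare_downstream(dset, cfg)
  rep3 <- repeated_evaluation(NULL, data, model_spec(18, 0.0625), cfg)
  expect_equal(nrow(rep3$per_run), 3)
  expect_length(rep3$test_idx, 8)
  expect_equal(as.numeric(rep3$mean["macro_f1"]),
               mean(rep3$per_run$macro_f1), tolerance = 1e-12)
  expect_true(all(c("f1_normal", "f1_af") %in% names(rep3$per_run)))
})

test_that("a single-lead encoder finetunes on 12-lead data end-to-end", {
  set.seed(4)
  dset <- generate_downstream_set(16, "multilabel12", seed = 19)
  cfg <- finetune_config(max_epochs = 2, early_stop_patience = 1,
                         checkpoint_criterion = "val_loss", target_fs = 250,
                         target_len_s = 10, batch_size = 4, seed = 4)
  data <- prepare_downstream(dset, cfg)
  expect_equal(dim(data$x)[1], 12)
  pre_enc <- build_encoder(model_spec(18, 0.0625))
  stem_w <- pre_enc$stem$par$w
  m0 <- ecgtl:::init_downstream_model(pre_enc, model_spec(18, 0.0625), 12,
                                      length(data$classes), "sigmoid")
  # adapted first layer satisfies the channel identity before any update
  expect_equal(m0$encoder$stem$par$w, adapt_conv_weights(stem_w, 12),
               tolerance = 1e-12)
  idx <- seq_len(dim(data$x)[3])
  ft <- run_finetune(pre_enc, data, idx[1:10], idx[11:16],
                     model_spec(18, 0.0625), cfg)
  expect_equal(ft$model$activation, "sigmoid")
  p <- classify(ft$model, data$x[, , 1:2, drop = FALSE])
  expect_true(all(p >= 0 & p <= 1))
  # multi-label metrics compute on held-out records
  out <- ecgtl:::evaluate_on_test(ft$model, data, idx[11:16], idx[1:10], cfg)
  expect_true(all(c("auc", "f_max", "f_beta", "g_beta") %in% names(out)))
  expect_true(all(out >= 0 & out <= 1))
})
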