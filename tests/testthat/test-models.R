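test_that("encoder output size and batch equivariance hold", {
  set.seed(1)
  enc <- build_encoder(model_spec(18, width_multiplier = 0.125))
  x <- array(rnorm(1 * 1024 * 3), c(1, 1024, 3))
  f <- ecgtl:::encoder_forward(enc, x, training = FALSE)
  expect_equal(dim(f), c(64, 3))   # 512 * 0.125
  xp <- x[, , c(3, 1, 2), drop = FALSE]
  fp <- ecgtl:::encoder_forward(enc, xp, training = FALSE)
  expect_equal(fp, f[, c(3, 1, 2)], tolerance = 1e-10)
})

test_that("invalid model specifications are rejected", {
  expect_error(model_spec(27), "depth")
  expect_error(model_spec(18, width_multiplier = 0), "positive")
  expect_error(model_spec(18, stages_used = 5), "stages_used")
  expect_error(replace_head(build_encoder(model_spec(18, 0.0625)), 1), ">= 2")
})

test_that("a truncated depth-50 encoder exposes the stage-3 width", {
  set.seed(2)
  enc <- build_encoder(model_spec(50, width_multiplier = 0.125, stages_used = 3))
  # bottleneck blocks expand stage width by 4: stage-3 output = 256*0.125*4
  expect_equal(enc$out_dim, 128)
  x <- array(rnorm(2048), c(1, 2048, 1))
  expect_equal(nrow(ecgtl:::encoder_forward(enc, x, training = FALSE)), 128)
})

test_that("parameter counts grow with depth at fixed width", {
  p18 <- n_parameters(build_encoder(model_spec(18, 0.25)))
  p34 <- n_parameters(build_encoder(model_spec(34, 0.25)))
  p50 <- n_parameters(build_encoder(model_spec(50, 0.25)))
  expect_lt(p18, p34)
  expect_lt(p34, p50)
})

test_that("classifier probabilities normalize and chance level holds untrained", {
  set.seed(3)
  m <- build_classifier(model_spec(18, 0.0625, n_classes = 4))
  x <- array(rnorm(1 * 512 * 8), c(1, 512, 8))
  p <- classify(m, x)
  expect_equal(dim(p), c(4, 8))
  expect_equal(colSums(p), rep(1, 8), tolerance = 1e-6)
  # untrained network on balanced random data sits at chance 0.25
  xb <- array(rnorm(1 * 256 * 2000), c(1, 256, 2000))
  yb <- rep(1:4, 500)
  pred <- apply(classify(m, xb), 2, which.max)
  expect_lt(abs(mean(pred == yb) - 0.25), 0.05)
})

test_that("head replacement keeps encoder weights bit-identical", {
  set.seed(4)
  m <- build_classifier(model_spec(18, 0.0625, n_classes = 4))
  stem_before <- m$encoder$stem$par$w
  m2 <- replace_head(m, 3, "sigmoid")
  expect_identical(m2$encoder$stem$par$w, stem_before)
  expect_equal(m2$spec$n_classes, 3)
  x <- array(rnorm(512), c(1, 512, 1))
  p <- classify(m2, x)
  expect_true(all(p >= 0 & p <= 1))
  expect_equal(nrow(p), 3)
})

test_that("a truncated pretrained encoder leaves stage 4 freshly initialized", {
  set.seed(5)
  trunc <- build_encoder(model_spec(50, 0.125, stages_used = 3))
  full <- build_encoder(model_spec(50, 0.125, stages_used = 4))
  s4_before <- Filter(function(b) b$stage == 4, full$blocks)[[1]]$conv1$par$w
  ecgtl:::init_encoder_from(full, trunc)
  s4_after <- Filter(function(b) b$stage == 4, full$blocks)[[1]]$conv1$par$w
  expect_identical(s4_after, s4_before)  # untouched by the copy
  # shared stages copied exactly
  expect_identical(full$stem$par$w, trunc$stem$par$w)
  b3_full <- Filter(function(b) b$stage == 3, full$blocks)[[1]]
  b3_trunc <- Filter(function(b) b$stage == 3, trunc$blocks)[[1]]
  expect_identical(b3_full$conv2$par$w, b3_trunc$conv2$par$w)
})

test_that("channel adaptation divides duplicated filters by the new count", {
  w <- matrix(0.6, 1, 1)
  wn <- adapt_conv_weights(w, 12)
  expect_equal(dim(wn), c(1, 12))
  expect_equal(as.numeric(wn), rep(0.05, 12))
  expect_equal(adapt_conv_weights(matrix(1:6, 2, 3), 1), matrix(1:6, 2, 3))
  expect_error(adapt_conv_weights(w, 0), ">= 1")
})

test_that("replicated single-lead input reproduces the single-channel output", {
  for (depth in c(18, 34, 50)) {
    set.seed(depth)
    enc1 <- build_encoder(model_spec(depth, 0.125))
    x1 <- array(rnorm(1024), c(1, 1024, 1))
    y1 <- ecgtl:::layer_forward(enc1$stem, x1, training = FALSE)
    adapt_input_channels(enc1, 12)
    x12 <- array(rep(x1, each = 12), c(12, 1024, 1))
    y12 <- ecgtl:::layer_forward(enc1$stem, x12, training = FALSE)
    expect_lt(max(abs(y12 - y1)), 1e-5)
  }
})

test_that("attention pooling has the contract size and is deterministic", {
  set.seed(6)
  ap <- build_attention_pool(attention_pool_spec(d_model = 64, n_heads = 8,
                                                 max_len = 16))
  ctx <- array(rnorm(64 * 8 * 2), c(64, 8, 2))
  c1 <- attention_pool(ap, ctx)
  c2 <- attention_pool(ap, ctx)
  expect_equal(dim(c1), c(64, 2))
  expect_identical(c1, c2)
  expect_error(attention_pool(ap, array(0, c(64, 0, 1))), "non-empty|context")
  expect_error(attention_pool_spec(d_model = 65, n_heads = 8), "divisible")
})

test_that("without positional embeddings the pooled vector is order invariant", {
  set.seed(7)
  ap <- build_attention_pool(attention_pool_spec(d_model = 32, n_heads = 4,
                                                 max_len = 16,
                                                 use_positional = FALSE))
  ctx <- array(rnorm(32 * 6), c(32, 6, 1))
  perm <- ctx[, c(4, 1, 6, 2, 5, 3), , drop = FALSE]
  expect_equal(attention_pool(ap, ctx), attention_pool(ap, perm),
               tolerance = 1e-10)
  # with positional embeddings the order matters
  set.seed(7)
  app <- build_attention_pool(attention_pool_spec(d_model = 32, n_heads = 4,
                                                  max_len = 16))
  expect_gt(max(abs(attention_pool(app, ctx) - attention_pool(app, perm))),
            1e-6)
})

test_that("contrastive probabilities normalize, saturate and permute correctly", {
  set.seed(8)
  # identical candidates: uniform 1/(ns+1)
  h <- matrix(rep(rnorm(16), 5), 16, 5)
  p <- cpc_probabilities(rnorm(16), h)
  expect_equal(p, rep(0.2, 5))
  # aligned positive with large scale dominates
  hpos <- rnorm(16)
  h2 <- cbind(hpos * 50, matrix(rnorm(16 * 3), 16, 3))
  expect_gt(cpc_probabilities(hpos * 50, h2)[1], 0.999)
  # loss is invariant to permuting negatives when the positive is tracked
  cvec <- rnorm(16)
  h3 <- matrix(rnorm(16 * 5), 16, 5)
  p3 <- cpc_probabilities(cvec, h3)
  perm <- c(1, 4, 2, 5, 3)  # positive stays at index 1
  p3p <- cpc_probabilities(cvec, h3[, perm])
  expect_equal(-log(p3[1]), -log(p3p[1]), tolerance = 1e-12)
  expect_equal(sum(p3), 1, tolerance = 1e-12)
  expect_error(cpc_probabilities(rnorm(8), matrix(0, 16, 3)), "mismatch")
})

test_that("checkpoints round-trip through disk with spec validation", {
  dir <- withr::local_tempdir()
  set.seed(9)
  m <- build_classifier(model_spec(18, 0.0625, n_classes = 4))
  x <- array(rnorm(512 * 2), c(1, 512, 2))
  p1 <- classify(m, x)
  save_checkpoint(m, file.path(dir, "ck"))
  m2 <- load_checkpoint(file.path(dir, "ck"))
  expect_equal(classify(m2, x), p1, tolerance = 1e-12)
  enc <- build_encoder(model_spec(34, 0.0625))
  save_checkpoint(enc, file.path(dir, "enc"))
  enc2 <- load_checkpoint(file.path(dir, "enc"))
  expect_identical(enc2$spec$depth, 34L)
  expect_equal(ecgtl:::encoder_forward(enc2, x, training = FALSE),
               ecgtl:::encoder_forward(enc, x, training = FALSE),
               tolerance = 1e-12)
})
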