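# Finite-difference checks of the hand-written backward passes. These pin
# the numerical core that everything else (pretraining, finetuning,
# contrastive learning) depends on.

num_grad_param <- function(l, name, idx, f, eps = 1e-5) {
  vapply(idx, function(i) {
    old <- l$par[[name]][i]
    l$par[[name]][i] <- old + eps; up <- f()
    l$par[[name]][i] <- old - eps; dn <- f()
    l$par[[name]][i] <- old
    (up - dn) / (2 * eps)
  }, 0)
}

test_that("convolution gradients match finite differences", {
  set.seed(1)
  l <- ecgtl:::nn_conv1d(2, 3, 5, stride = 2)
  x <- array(rnorm(2 * 16 * 2), c(2, 16, 2))
  w <- array(rnorm(3 * 8 * 2), c(3, 8, 2))
  ecgtl:::zero_grad(list(l))
  ecgtl:::layer_forward(l, x)
  dx <- ecgtl:::layer_backward(l, w)
  f <- function() sum(ecgtl:::layer_forward(l, x) * w)
  idx <- sample(length(l$par$w), 8)
  expect_lt(max(abs(num_grad_param(l, "w", idx, f) - l$grad$w[idx])), 1e-6)
  expect_lt(max(abs(num_grad_param(l, "b", 1:3, f) - l$grad$b[1:3])), 1e-6)
  idx <- sample(length(x), 8)
  gx <- vapply(idx, function(i) {
    x2 <- x; x2[i] <- x2[i] + 1e-5; up <- sum(ecgtl:::layer_forward(l, x2) * w)
    x2[i] <- x2[i] - 2e-5; dn <- sum(ecgtl:::layer_forward(l, x2) * w)
    (up - dn) / 2e-5
  }, 0)
  expect_lt(max(abs(gx - dx[idx])), 1e-6)
})

test_that("batchnorm, attention pooling and end-to-end encoder gradients match", {
  set.seed(2)
  # batchnorm input gradient
  lb <- ecgtl:::nn_bn(3)
  xb <- array(rnorm(3 * 8 * 4), c(3, 8, 4))
  wb <- array(rnorm(3 * 8 * 4), c(3, 8, 4))
  ecgtl:::zero_grad(list(lb))
  ecgtl:::layer_forward(lb, xb)
  dxb <- ecgtl:::layer_backward(lb, wb)
  lb2 <- ecgtl:::nn_bn(3)
  idx <- sample(length(xb), 10)
  gx <- vapply(idx, function(i) {
    x2 <- xb; x2[i] <- x2[i] + 1e-5
    up <- sum(ecgtl:::layer_forward(lb2, x2) * wb)
    x2[i] <- x2[i] - 2e-5
    dn <- sum(ecgtl:::layer_forward(lb2, x2) * wb)
    (up - dn) / 2e-5
  }, 0)
  expect_lt(max(abs(gx - dxb[idx])), 1e-6)

  # end-to-end classifier loss gradient wrt stem and a mid-block weight
  spec <- model_spec(18, width_multiplier = 0.0625, n_classes = 3)
  m <- build_classifier(spec)
  xe <- array(rnorm(64 * 2), c(1, 64, 2))
  ye <- c(1L, 3L)
  layers <- ecgtl:::model_layers(m)
  loss <- function() {
    z <- ecgtl:::model_logits(m, xe, training = TRUE)
    ecgtl:::cross_entropy(z, ye)$loss
  }
  ecgtl:::zero_grad(layers)
  z <- ecgtl:::model_logits(m, xe, training = TRUE)
  ce <- ecgtl:::cross_entropy(z, ye)
  dfeat <- ecgtl:::layer_backward(m$head, ce$dlogits)
  ecgtl:::encoder_backward(m$encoder, dfeat)
  for (l in list(m$encoder$stem, m$encoder$blocks[[3]]$conv1, m$head)) {
    idx <- sample(length(l$par$w), 6)
    expect_lt(max(abs(num_grad_param(l, "w", idx, loss) - l$grad$w[idx])), 1e-5)
  }

  # attention pooling: context gradient and token/mha parameter gradients
  ap <- build_attention_pool(attention_pool_spec(d_model = 16, n_layers = 2,
                                                 n_heads = 4, max_len = 8))
  ctx <- array(rnorm(16 * 4 * 2), c(16, 4, 2))
  wc <- matrix(rnorm(16 * 2), 16, 2)
  apl <- ecgtl:::attention_pool_layers(ap)
  ecgtl:::zero_grad(apl)
  attention_pool(ap, ctx)
  dctx <- ecgtl:::attention_pool_backward(ap, wc)
  fap <- function() sum(attention_pool(ap, ctx) * wc)
  idx <- sample(length(ctx), 10)
  gctx <- vapply(idx, function(i) {
    c2 <- ctx; c2[i] <- c2[i] + 1e-5; up <- sum(attention_pool(ap, c2) * wc)
    c2[i] <- c2[i] - 2e-5; dn <- sum(attention_pool(ap, c2) * wc)
    (up - dn) / 2e-5
  }, 0)
  expect_lt(max(abs(gctx - dctx[idx])), 1e-6)
  mha <- ap$layers[[1]]$mha
  idx <- sample(length(mha$par$wq), 6)
  expect_lt(max(abs(num_grad_param(mha, "wq", idx, fap) - mha$grad$wq[idx])), 1e-6)
  expect_lt(max(abs(num_grad_param(ap$tok, "c0", 1:6, fap) -
                      ap$tok$grad$c0[1:6])), 1e-6)
})

test_that("adam with default hyperparameters reduces a convex loss", {
  set.seed(3)
  l <- ecgtl:::nn_dense(4, 1)
  target <- matrix(rnorm(4), 1, 4)
  x <- diag(4)
  opt <- ecgtl:::adam_new(list(l), lr = 0.05)
  losses <- numeric(100)
  for (i in 1:100) {
    ecgtl:::zero_grad(list(l))
    y <- ecgtl:::layer_forward(l, x)
    d <- y - target %*% x  # match each coordinate
    losses[i] <- mean(d^2)
    ecgtl:::layer_backward(l, 2 * d / length(d))
    ecgtl:::adam_step(opt)
  }
  expect_lt(losses[100], losses[1] * 0.05)
})
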