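#' @useDynLib ecgtl, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Lightweight neural-network core.
#
# Feature maps are arrays of shape (channels, length, batch); vector features
# are matrices of shape (features, batch). Every layer is an environment
# holding parameters (`par`), accumulated gradients (`grad`), Adam moments
# (`m`, `v`) and a forward cache, so that backward passes and optimizer steps
# mutate in place.

new_layer <- function(type, par = list(), hyper = list()) {
  l <- new.env(parent = emptyenv())
  l$type <- type
  l$par <- par
  l$grad <- lapply(par, function(p) p * 0)
  l$hyper <- hyper
  l$cache <- NULL
  class(l) <- "ecgtl_layer"
  l
}

# He-style normal init for convolution / dense weights
init_weight <- function(nrow, ncol, fan_in, rng_sd = sqrt(2)) {
  matrix(stats::rnorm(nrow * ncol, sd = rng_sd / sqrt(fan_in)), nrow, ncol)
}

nn_conv1d <- function(in_ch, out_ch, k, stride = 1L, pad = (k - 1L) %/% 2L,
                      init = c("he", "zero")) {
  init <- match.arg(init)
  w <- if (init == "he") init_weight(out_ch, in_ch * k, in_ch * k)
       else matrix(0, out_ch, in_ch * k)
  new_layer("conv",
            par = list(w = w, b = numeric(out_ch)),
            hyper = list(in_ch = in_ch, out_ch = out_ch, k = as.integer(k),
                         stride = as.integer(stride), pad = as.integer(pad)))
}

nn_bn <- function(ch, momentum = 0.9, eps = 1e-5) {
  l <- new_layer("bn", par = list(gamma = rep(1, ch), beta = rep(0, ch)),
                 hyper = list(ch = ch, momentum = momentum, eps = eps))
  l$running_mean <- rep(0, ch)
  l$running_var <- rep(1, ch)
  l
}

nn_relu <- function() new_layer("relu")
nn_maxpool <- function(k = 3L, stride = 2L, pad = 1L)
  new_layer("maxpool", hyper = list(k = as.integer(k), stride = as.integer(stride),
                                    pad = as.integer(pad)))
nn_gap <- function() new_layer("gap")

nn_dense <- function(in_dim, out_dim, init = c("he", "zero")) {
  init <- match.arg(init)
  w <- if (init == "he") init_weight(out_dim, in_dim, in_dim) else matrix(0, out_dim, in_dim)
  new_layer("dense", par = list(w = w, b = numeric(out_dim)),
            hyper = list(in_dim = in_dim, out_dim = out_dim))
}

layer_forward <- function(l, x, training = TRUE) {
  switch(l$type,
    conv = {
      h <- l$hyper
      y <- cpp_conv1d_forward(x, l$par$w, l$par$b, h$k, h$stride, h$pad)
      l$cache <- list(x = x)
      y
    },
    bn = {
      h <- l$hyper
      d <- dim(x)
      xm <- matrix(x, d[1], d[2] * d[3])
      if (training) {
        mu <- rowMeans(xm)
        va <- rowMeans(xm * xm) - mu * mu
        l$running_mean <- h$momentum * l$running_mean + (1 - h$momentum) * mu
        l$running_var <- h$momentum * l$running_var + (1 - h$momentum) * va
      } else {
        mu <- l$running_mean
        va <- l$running_var
      }
      istd <- 1 / sqrt(va + h$eps)
      xhat <- (xm - mu) * istd
      y <- array(l$par$gamma * xhat + l$par$beta, dim = d)
      if (training) l$cache <- list(xhat = xhat, istd = istd, dims = d)
      y
    },
    relu = {
      mask <- x > 0
      l$cache <- list(mask = mask)
      x * mask
    },
    maxpool = {
      h <- l$hyper
      out <- cpp_maxpool_forward(x, h$k, h$stride, h$pad)
      l$cache <- list(argmax = out$argmax, l_in = dim(x)[2])
      out$y
    },
    gap = {
      d <- dim(x)
      l$cache <- list(dims = d)
      colMeans(aperm(x, c(2L, 1L, 3L)), dims = 1L)
    },
    dense = {
      l$cache <- list(x = x)
      l$par$w %*% x + l$par$b
    },
    stop("unknown layer type: ", l$type))
}

layer_backward <- function(l, dy) {
  switch(l$type,
    conv = {
      h <- l$hyper
      gr <- cpp_conv1d_backward(dy, l$cache$x, l$par$w, h$k, h$stride, h$pad)
      l$grad$w <- l$grad$w + gr$dw
      l$grad$b <- l$grad$b + as.numeric(gr$db)
      gr$dx
    },
    bn = {
      cc <- l$cache
      d <- cc$dims
      n <- d[2] * d[3]
      dym <- matrix(dy, d[1], n)
      l$grad$gamma <- l$grad$gamma + rowSums(dym * cc$xhat)
      l$grad$beta <- l$grad$beta + rowSums(dym)
      dxhat <- dym * l$par$gamma
      s1 <- rowSums(dxhat)
      s2 <- rowSums(dxhat * cc$xhat)
      dx <- (cc$istd / n) * (n * dxhat - s1 - cc$xhat * s2)
      array(dx, dim = d)
    },
    relu = dy * l$cache$mask,
    maxpool = cpp_maxpool_backward(dy, l$cache$argmax, l$cache$l_in),
    gap = {
      d <- l$cache$dims
      dx <- array(0, dim = d)
      scale <- 1 / d[2]
      for (b in seq_len(d[3])) dx[, , b] <- matrix(dy[, b], d[1], d[2]) * scale
      dx
    },
    dense = {
      l$grad$w <- l$grad$w + dy %*% t(l$cache$x)
      l$grad$b <- l$grad$b + rowSums(dy)
      t(l$par$w) %*% dy
    },
    stop("unknown layer type: ", l$type))
}

zero_grad <- function(layers) {
  for (l in layers) {
    for (nm in names(l$grad)) l$grad[[nm]][] <- 0
  }
  invisible(NULL)
}

# --- Adam optimizer (default hyperparameters) --------------------------------

adam_new <- function(layers, lr = 1e-3, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (l in layers) {
    l$m <- lapply(l$par, function(p) p * 0)
    l$v <- lapply(l$par, function(p) p * 0)
  }
  opt <- new.env(parent = emptyenv())
  opt$layers <- layers
  opt$lr <- lr; opt$beta1 <- beta1; opt$beta2 <- beta2; opt$eps <- eps
  opt$t <- 0L
  opt
}

adam_step <- function(opt) {
  opt$t <- opt$t + 1L
  b1 <- opt$beta1; b2 <- opt$beta2
  c1 <- 1 - b1^opt$t
  c2 <- 1 - b2^opt$t
  for (l in opt$layers) {
    for (nm in names(l$par)) {
      g <- l$grad[[nm]]
      l$m[[nm]] <- b1 * l$m[[nm]] + (1 - b1) * g
      l$v[[nm]] <- b2 * l$v[[nm]] + (1 - b2) * g * g
      l$par[[nm]] <- l$par[[nm]] -
        opt$lr * (l$m[[nm]] / c1) / (sqrt(l$v[[nm]] / c2) + opt$eps)
    }
  }
  invisible(NULL)
}

# --- losses ------------------------------------------------------------------

# logits: (n_classes, batch); target: integer class in 1..n_classes
softmax_cols <- function(z) {
  z <- sweep(z, 2, apply(z, 2, max))
  e <- exp(z)
  sweep(e, 2, colSums(e), "/")
}

cross_entropy <- function(logits, target) {
  p <- softmax_cols(logits)
  b <- ncol(logits)
  idx <- cbind(target, seq_len(b))
  loss <- -mean(log(pmax(p[idx], 1e-12)))
  dlogits <- p
  dlogits[idx] <- dlogits[idx] - 1
  list(loss = loss, dlogits = dlogits / b, prob = p)
}

# logits: (n_classes, batch); target: 0/1 matrix of same shape
binary_cross_entropy <- function(logits, target) {
  p <- 1 / (1 + exp(-logits))
  n <- length(logits)
  loss <- -mean(target * log(pmax(p, 1e-12)) + (1 - target) * log(pmax(1 - p, 1e-12)))
  list(loss = loss, dlogits = (p - target) / n, prob = p)
}

# --- (de)serialization helpers ----------------------------------------------

layer_state <- function(l) {
  st <- list(par = l$par)
  if (l$type == "bn") {
    st$running_mean <- l$running_mean
    st$running_var <- l$running_var
  }
  st
}

layer_load_state <- function(l, st) {
  l$par <- st$par
  l$grad <- lapply(st$par, function(p) p * 0)
  if (l$type == "bn") {
    l$running_mean <- st$running_mean
    l$running_var <- st$running_var
  }
  invisible(l)
}
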