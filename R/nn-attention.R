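# Transformer attention pooling: a learnable context token is prepended to
# the encoded context frames, the sequence runs through N Transformer encoder
# layers (multi-head self-attention + position-wise feed-forward, post-layer
# normalization), and the output at the token position is the pooled context
# vector. Learned positional embeddings are added by default (future
# prediction is order-sensitive); they can be disabled, which makes the
# pooled vector invariant to permutations of the context order.

#' Attention-pooling specification
#'
#' Defaults follow the compact Transformer used for contrastive future
#' prediction: N = 3 layers, 8 attention heads, feed-forward width twice the
#' model width, no dropout. `d_model` must equal the encoder feature size.
#'
#' @param d_model model (and encoder feature) dimensionality
#' @param n_layers number of Transformer layers
#' @param n_heads attention heads; must divide d_model
#' @param d_ff feed-forward inner width (default 2 * d_model)
#' @param max_len maximum context length supported by positional embeddings
#' @param use_positional add learned positional embeddings (default TRUE)
#' @return an `attention_pool_spec` list
#' @export
attention_pool_spec <- function(d_model = 512L, n_layers = 3L, n_heads = 8L,
                                d_ff = 2L * d_model, max_len = 64L,
                                use_positional = TRUE) {
  d_model <- as.integer(d_model)
  if (d_model %% n_heads != 0L) stop("d_model must be divisible by n_heads")
  structure(list(d_model = d_model, n_layers = as.integer(n_layers),
                 n_heads = as.integer(n_heads), d_ff = as.integer(d_ff),
                 max_len = as.integer(max_len),
                 use_positional = isTRUE(use_positional)),
            class = "attention_pool_spec")
}

nn_layernorm <- function(d, eps = 1e-5) {
  new_layer("layernorm", par = list(gamma = rep(1, d), beta = rep(0, d)),
            hyper = list(d = d, eps = eps))
}

# x: matrix (d, n); normalize each column over the feature dimension
layernorm_forward <- function(l, x) {
  d <- l$hyper$d
  mu <- colMeans(x)
  xc <- sweep(x, 2, mu)
  va <- colMeans(xc * xc)
  istd <- 1 / sqrt(va + l$hyper$eps)
  xhat <- sweep(xc, 2, istd, "*")
  l$cache <- list(xhat = xhat, istd = istd)
  l$par$gamma * xhat + l$par$beta
}

layernorm_backward <- function(l, dy) {
  cc <- l$cache
  d <- l$hyper$d
  l$grad$gamma <- l$grad$gamma + rowSums(dy * cc$xhat)
  l$grad$beta <- l$grad$beta + rowSums(dy)
  dxhat <- dy * l$par$gamma
  s1 <- colSums(dxhat)
  s2 <- colSums(dxhat * cc$xhat)
  t((t(dxhat) * d - s1 - t(cc$xhat) * s2) * (cc$istd / d))
}

nn_mha <- function(d, h) {
  new_layer("mha",
            par = list(wq = init_weight(d, d, d, 1), bq = numeric(d),
                       wk = init_weight(d, d, d, 1), bk = numeric(d),
                       wv = init_weight(d, d, d, 1), bv = numeric(d),
                       wo = init_weight(d, d, d, 1), bo = numeric(d)),
            hyper = list(d = d, h = h, dk = d %/% h))
}

# x: array (d, T, B)
mha_forward <- function(l, x) {
  d <- l$hyper$d; h <- l$hyper$h; dk <- l$hyper$dk
  dm <- dim(x)
  tt <- dm[2]; nb <- dm[3]
  y <- array(0, dm)
  cache <- vector("list", nb)
  for (b in seq_len(nb)) {
    xb <- matrix(x[, , b], d, tt)
    q <- l$par$wq %*% xb + l$par$bq
    k <- l$par$wk %*% xb + l$par$bk
    v <- l$par$wv %*% xb + l$par$bv
    o <- matrix(0, d, tt)
    aheads <- vector("list", h)
    for (i in seq_len(h)) {
      rows <- (i - 1L) * dk + seq_len(dk)
      s <- crossprod(k[rows, , drop = FALSE], q[rows, , drop = FALSE]) / sqrt(dk)
      a <- apply(s, 2, function(col) { e <- exp(col - max(col)); e / sum(e) })
      a <- matrix(a, tt, tt)
      o[rows, ] <- v[rows, , drop = FALSE] %*% a
      aheads[[i]] <- a
    }
    y[, , b] <- l$par$wo %*% o + l$par$bo
    cache[[b]] <- list(xb = xb, q = q, k = k, v = v, o = o, a = aheads)
  }
  l$cache <- cache
  y
}

mha_backward <- function(l, dy) {
  d <- l$hyper$d; h <- l$hyper$h; dk <- l$hyper$dk
  dm <- dim(dy)
  tt <- dm[2]; nb <- dm[3]
  dx <- array(0, dm)
  for (b in seq_len(nb)) {
    cc <- l$cache[[b]]
    dyb <- matrix(dy[, , b], d, tt)
    l$grad$wo <- l$grad$wo + dyb %*% t(cc$o)
    l$grad$bo <- l$grad$bo + rowSums(dyb)
    do <- t(l$par$wo) %*% dyb
    dq <- matrix(0, d, tt); dkm <- matrix(0, d, tt); dv <- matrix(0, d, tt)
    for (i in seq_len(h)) {
      rows <- (i - 1L) * dk + seq_len(dk)
      a <- cc$a[[i]]
      doi <- do[rows, , drop = FALSE]
      dv[rows, ] <- doi %*% t(a)
      da <- crossprod(cc$v[rows, , drop = FALSE], doi)   # (T, T)
      ds <- a * (da - matrix(colSums(a * da), tt, tt, byrow = TRUE))
      dq[rows, ] <- (cc$k[rows, , drop = FALSE] %*% ds) / sqrt(dk)
      dkm[rows, ] <- (cc$q[rows, , drop = FALSE] %*% t(ds)) / sqrt(dk)
    }
    l$grad$wq <- l$grad$wq + dq %*% t(cc$xb); l$grad$bq <- l$grad$bq + rowSums(dq)
    l$grad$wk <- l$grad$wk + dkm %*% t(cc$xb); l$grad$bk <- l$grad$bk + rowSums(dkm)
    l$grad$wv <- l$grad$wv + dv %*% t(cc$xb); l$grad$bv <- l$grad$bv + rowSums(dv)
    dx[, , b] <- t(l$par$wq) %*% dq + t(l$par$wk) %*% dkm + t(l$par$wv) %*% dv
  }
  dx
}

new_transformer_layer <- function(d, h, d_ff) {
  tl <- new.env(parent = emptyenv())
  tl$mha <- nn_mha(d, h)
  tl$ln1 <- nn_layernorm(d)
  tl$ff1 <- nn_dense(d, d_ff)
  tl$relu <- nn_relu()
  tl$ff2 <- nn_dense(d_ff, d)
  tl$ln2 <- nn_layernorm(d)
  tl
}

transformer_layer_forward <- function(tl, x) {
  dm <- dim(x)
  att <- mha_forward(tl$mha, x)
  h1 <- matrix(x + att, dm[1], dm[2] * dm[3])
  y1 <- layernorm_forward(tl$ln1, h1)
  f <- layer_forward(tl$ff2, layer_forward(tl$relu, layer_forward(tl$ff1, y1)))
  y2 <- layernorm_forward(tl$ln2, y1 + f)
  array(y2, dm)
}

transformer_layer_backward <- function(tl, dy) {
  dm <- dim(dy)
  dym <- matrix(dy, dm[1], dm[2] * dm[3])
  dh2 <- layernorm_backward(tl$ln2, dym)
  df <- layer_backward(tl$ff1, layer_backward(tl$relu, layer_backward(tl$ff2, dh2)))
  dy1 <- dh2 + df
  dh1 <- layernorm_backward(tl$ln1, dy1)
  datt <- mha_backward(tl$mha, array(dh1, dm))
  datt + array(dh1, dm)
}

transformer_layer_layers <- function(tl) list(tl$mha, tl$ln1, tl$ff1, tl$ff2, tl$ln2)

#' Build an attention-pooling module
#'
#' @param spec an [attention_pool_spec()]
#' @return an attention-pool object
#' @export
build_attention_pool <- function(spec) {
  stopifnot(inherits(spec, "attention_pool_spec"))
  ap <- new.env(parent = emptyenv())
  ap$spec <- spec
  d <- spec$d_model
  ap$tok <- new_layer("embed",
                      par = list(c0 = stats::rnorm(d, sd = 1 / sqrt(d)),
                                 pos = matrix(stats::rnorm(d * (spec$max_len + 1L),
                                                           sd = 1 / sqrt(d)),
                                              d, spec$max_len + 1L)))
  ap$layers <- lapply(seq_len(spec$n_layers),
                      function(i) new_transformer_layer(d, spec$n_heads, spec$d_ff))
  class(ap) <- "ecgtl_attention_pool"
  ap
}

attention_pool_layers <- function(ap) {
  c(list(ap$tok), unlist(lapply(ap$layers, transformer_layer_layers)))
}

#' Pool a sequence of context encodings into a single context vector
#'
#' @param ap attention-pool object
#' @param ctx array (d_model, K, batch) of encoded context frames
#' @return matrix (d_model, batch): the output at the context-token position
#' @export
attention_pool <- function(ap, ctx) {
  d <- ap$spec$d_model
  if (length(dim(ctx)) != 3L || dim(ctx)[1] != d) stop("ctx must be (d_model, K, batch)")
  kk <- dim(ctx)[2]; nb <- dim(ctx)[3]
  if (kk < 1L) stop("context must be non-empty")
  if (kk + 1L > ncol(ap$tok$par$pos)) stop("context longer than positional table")
  x <- array(0, c(d, kk + 1L, nb))
  for (b in seq_len(nb)) x[, , b] <- cbind(ap$tok$par$c0, matrix(ctx[, , b], d, kk))
  if (ap$spec$use_positional) {
    pe <- ap$tok$par$pos[, seq_len(kk + 1L), drop = FALSE]
    for (b in seq_len(nb)) x[, , b] <- x[, , b] + pe
  }
  for (tl in ap$layers) x <- transformer_layer_forward(tl, x)
  ap$cache_k <- kk
  matrix(x[, 1L, ], d, nb)
}

attention_pool_backward <- function(ap, dc) {
  d <- ap$spec$d_model
  kk <- ap$cache_k; nb <- ncol(dc)
  dx <- array(0, c(d, kk + 1L, nb))
  dx[, 1L, ] <- dc
  for (tl in rev(ap$layers)) dx <- transformer_layer_backward(tl, dx)
  if (ap$spec$use_positional) {
    pe_grad <- apply(dx, c(1, 2), sum)
    ap$tok$grad$pos[, seq_len(kk + 1L)] <-
      ap$tok$grad$pos[, seq_len(kk + 1L), drop = FALSE] + pe_grad
  }
  ap$tok$grad$c0 <- ap$tok$grad$c0 + rowSums(matrix(dx[, 1L, ], d, nb))
  array(dx[, -1L, , drop = FALSE], c(d, kk, nb))
}

#' Contrastive probabilities over future-frame candidates
#'
#' The similarity between the pooled context vector and each candidate
#' encoding is their (unscaled) dot product; a softmax over candidates gives
#' the probability of each candidate being the true future frame.
#'
#' @param c_vec context vector (length d) or matrix (d, batch)
#' @param h matrix (d, n_candidates) or array (d, n_candidates, batch)
#' @return probability vector / matrix over candidates (columns are examples)
#' @export
cpc_probabilities <- function(c_vec, h) {
  if (is.null(dim(c_vec))) c_vec <- matrix(c_vec, ncol = 1L)
  if (length(dim(h)) == 2L) h <- array(h, c(dim(h), 1L))
  if (dim(h)[1] != nrow(c_vec)) stop("dimension mismatch between context and candidates")
  nb <- ncol(c_vec)
  p <- matrix(0, dim(h)[2], nb)
  for (b in seq_len(nb)) {
    z <- as.numeric(t(h[, , b]) %*% c_vec[, b])
    e <- exp(z - max(z))
    p[, b] <- e / sum(e)
  }
  if (nb == 1L) drop(p) else p
}
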