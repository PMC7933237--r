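# 1D pre-activation residual encoders ("v2" ordering: norm -> nonlinearity ->
# convolution), ported to one-dimensional signals. Stage filter sizes are
# 7, 5, 5 and 3; downsampling happens in the stem (stride-2 convolution plus
# stride-2 max-pool) and at the entry of stages 2-4.

RESNET_BLOCKS <- list(`18` = c(2L, 2L, 2L, 2L),
                      `34` = c(3L, 4L, 6L, 3L),
                      `50` = c(3L, 4L, 6L, 3L))
STAGE_FILTERS <- c(7L, 5L, 5L, 3L)
BASE_WIDTHS <- c(64L, 128L, 256L, 512L)

#' Residual-encoder specification
#'
#' Describes a 1D residual network: depth (18/34 use basic blocks, 50 uses
#' bottleneck blocks), a width multiplier for desk-scale runs (1.0 reproduces
#' the reference stage widths 64/128/256/512), the number of input channels
#' (ECG leads) and, optionally, how many stages to build (truncated encoders
#' are used when contrastive pretraining the deepest network).
#'
#' @param depth one of 18, 34, 50
#' @param width_multiplier positive scaling of all stage widths
#' @param in_channels number of input channels (leads), >= 1
#' @param n_classes classifier output size, or NULL for a bare encoder
#' @param stages_used number of residual stages to build (1-4)
#' @return a `model_spec` list
#' @export
model_spec <- function(depth = 18L, width_multiplier = 1, in_channels = 1L,
                       n_classes = NULL, stages_used = 4L) {
  depth <- as.integer(depth)
  if (!depth %in% c(18L, 34L, 50L)) stop("depth must be 18, 34 or 50")
  if (width_multiplier <= 0) stop("width_multiplier must be positive")
  if (in_channels < 1L) stop("in_channels must be >= 1")
  if (!stages_used %in% 1:4) stop("stages_used must be in 1..4")
  widths <- pmax(1L, as.integer(round(BASE_WIDTHS * width_multiplier)))
  structure(list(depth = depth, width_multiplier = width_multiplier,
                 in_channels = as.integer(in_channels),
                 n_classes = if (is.null(n_classes)) NULL else as.integer(n_classes),
                 stages_used = as.integer(stages_used),
                 widths = widths,
                 filters = STAGE_FILTERS,
                 bottleneck = depth == 50L,
                 blocks = RESNET_BLOCKS[[as.character(depth)]]),
            class = "model_spec")
}

new_basic_block <- function(in_ch, out_ch, k, stride, stage) {
  down <- stride > 1L || in_ch != out_ch
  b <- new.env(parent = emptyenv())
  b$kind <- "basic"; b$stage <- stage
  b$bn1 <- nn_bn(in_ch); b$relu1 <- nn_relu()
  b$conv1 <- nn_conv1d(in_ch, out_ch, k, stride = stride)
  b$bn2 <- nn_bn(out_ch); b$relu2 <- nn_relu()
  b$conv2 <- nn_conv1d(out_ch, out_ch, k, stride = 1L)
  b$sc <- if (down) nn_conv1d(in_ch, out_ch, 1L, stride = stride, pad = 0L) else NULL
  b
}

new_bottleneck_block <- function(in_ch, mid_ch, k, stride, stage) {
  out_ch <- 4L * mid_ch
  down <- stride > 1L || in_ch != out_ch
  b <- new.env(parent = emptyenv())
  b$kind <- "bottleneck"; b$stage <- stage
  b$bn1 <- nn_bn(in_ch); b$relu1 <- nn_relu()
  b$conv1 <- nn_conv1d(in_ch, mid_ch, 1L, stride = 1L, pad = 0L)
  b$bn2 <- nn_bn(mid_ch); b$relu2 <- nn_relu()
  b$conv2 <- nn_conv1d(mid_ch, mid_ch, k, stride = stride)
  b$bn3 <- nn_bn(mid_ch); b$relu3 <- nn_relu()
  b$conv3 <- nn_conv1d(mid_ch, out_ch, 1L, stride = 1L, pad = 0L)
  b$sc <- if (down) nn_conv1d(in_ch, out_ch, 1L, stride = stride, pad = 0L) else NULL
  b
}

block_forward <- function(b, x, training = TRUE) {
  a <- layer_forward(b$relu1, layer_forward(b$bn1, x, training), training)
  h <- layer_forward(b$conv1, a, training)
  h <- layer_forward(b$relu2, layer_forward(b$bn2, h, training), training)
  h <- layer_forward(b$conv2, h, training)
  if (b$kind == "bottleneck") {
    h <- layer_forward(b$relu3, layer_forward(b$bn3, h, training), training)
    h <- layer_forward(b$conv3, h, training)
  }
  sc <- if (is.null(b$sc)) x else layer_forward(b$sc, a, training)
  h + sc
}

block_backward <- function(b, dy) {
  if (b$kind == "bottleneck") {
    dh <- layer_backward(b$conv3, dy)
    dh <- layer_backward(b$bn3, layer_backward(b$relu3, dh))
  } else {
    dh <- dy
  }
  dh <- layer_backward(b$conv2, dh)
  dh <- layer_backward(b$bn2, layer_backward(b$relu2, dh))
  da <- layer_backward(b$conv1, dh)
  if (is.null(b$sc)) {
    dx_sc <- dy
  } else {
    da <- da + layer_backward(b$sc, dy)
    dx_sc <- 0
  }
  layer_backward(b$bn1, layer_backward(b$relu1, da)) + dx_sc
}

block_layers <- function(b) {
  ls <- list(b$bn1, b$conv1, b$bn2, b$conv2)
  if (b$kind == "bottleneck") ls <- c(ls, list(b$bn3, b$conv3))
  if (!is.null(b$sc)) ls <- c(ls, list(b$sc))
  ls
}

#' Build a 1D residual encoder
#'
#' Stem: kernel-7 stride-2 convolution followed by a stride-2 max-pool.
#' Four (or fewer, for truncated specs) pre-activation stages, a final
#' norm + nonlinearity and global average pooling. Weights use He-style
#' initialization.
#'
#' @param spec a [model_spec()]
#' @return an encoder object; its feature size is in `$out_dim`
#' @export
build_encoder <- function(spec) {
  stopifnot(inherits(spec, "model_spec"))
  enc <- new.env(parent = emptyenv())
  enc$spec <- spec
  enc$stem <- nn_conv1d(spec$in_channels, spec$widths[1], 7L, stride = 2L, pad = 3L)
  enc$pool <- nn_maxpool(3L, 2L, 1L)
  blocks <- list()
  in_ch <- spec$widths[1]
  for (s in seq_len(spec$stages_used)) {
    k <- spec$filters[s]
    for (i in seq_len(spec$blocks[s])) {
      stride <- if (s > 1L && i == 1L) 2L else 1L
      bl <- if (spec$bottleneck) new_bottleneck_block(in_ch, spec$widths[s], k, stride, s)
            else new_basic_block(in_ch, spec$widths[s], k, stride, s)
      in_ch <- if (spec$bottleneck) 4L * spec$widths[s] else spec$widths[s]
      blocks[[length(blocks) + 1L]] <- bl
    }
  }
  enc$blocks <- blocks
  enc$bn_final <- nn_bn(in_ch)
  enc$relu_final <- nn_relu()
  enc$gap <- nn_gap()
  enc$out_dim <- in_ch
  class(enc) <- "ecgtl_encoder"
  enc
}

encoder_forward <- function(enc, x, training = TRUE) {
  h <- layer_forward(enc$stem, x, training)
  h <- layer_forward(enc$pool, h, training)
  for (b in enc$blocks) h <- block_forward(b, h, training)
  h <- layer_forward(enc$relu_final, layer_forward(enc$bn_final, h, training), training)
  layer_forward(enc$gap, h, training)
}

encoder_backward <- function(enc, dfeat) {
  dh <- layer_backward(enc$gap, dfeat)
  dh <- layer_backward(enc$bn_final, layer_backward(enc$relu_final, dh))
  for (b in rev(enc$blocks)) dh <- block_backward(b, dh)
  dh <- layer_backward(enc$pool, dh)
  layer_backward(enc$stem, dh)
}

encoder_layers <- function(enc) {
  c(list(enc$stem), unlist(lapply(enc$blocks, block_layers)),
    list(enc$bn_final))
}

#' Number of trainable parameters
#' @param x an encoder or classifier model
#' @return integer parameter count
#' @export
n_parameters <- function(x) {
  ls <- if (inherits(x, "ecgtl_encoder")) encoder_layers(x) else model_layers(x)
  sum(vapply(ls, function(l) sum(vapply(l$par, length, 1L)), 1))
}

# --- classifier = encoder + fully connected head -----------------------------

#' Build a classifier (encoder + fully connected head)
#'
#' @param spec a [model_spec()] with non-NULL `n_classes`
#' @param activation "softmax" for single-label, "sigmoid" for multi-label
#' @return a classifier model
#' @export
build_classifier <- function(spec, activation = c("softmax", "sigmoid")) {
  activation <- match.arg(activation)
  if (is.null(spec$n_classes)) stop("spec$n_classes must be set for a classifier")
  m <- new.env(parent = emptyenv())
  m$encoder <- build_encoder(spec)
  m$head <- nn_dense(m$encoder$out_dim, spec$n_classes)
  m$activation <- activation
  m$spec <- spec
  class(m) <- "ecgtl_classifier"
  m
}

model_layers <- function(m) c(encoder_layers(m$encoder), list(m$head))

model_logits <- function(m, x, training = TRUE) {
  layer_forward(m$head, encoder_forward(m$encoder, x, training), training)
}

#' Class probabilities for a batch of frames
#'
#' @param model a classifier model
#' @param x array (channels, length, batch)
#' @return matrix (n_classes, batch); columns sum to 1 for softmax heads
#' @export
classify <- function(model, x) {
  z <- model_logits(model, x, training = FALSE)
  if (model$activation == "softmax") softmax_cols(z) else 1 / (1 + exp(-z))
}

#' Replace the classification head of a model
#'
#' The output layer is replaced by a freshly initialized fully connected
#' layer; encoder weights are left untouched (finetuning is end-to-end,
#' nothing is frozen).
#'
#' @param model a classifier model or bare encoder
#' @param n_classes new output size (>= 2)
#' @param activation "softmax" or "sigmoid"
#' @return a classifier model sharing the encoder
#' @export
replace_head <- function(model, n_classes, activation = c("softmax", "sigmoid")) {
  activation <- match.arg(activation)
  if (n_classes < 2L) stop("n_classes must be >= 2")
  enc <- if (inherits(model, "ecgtl_classifier")) model$encoder else model
  m <- new.env(parent = emptyenv())
  m$encoder <- enc
  m$head <- nn_dense(enc$out_dim, as.integer(n_classes))
  m$activation <- activation
  m$spec <- enc$spec
  m$spec$n_classes <- as.integer(n_classes)
  class(m) <- "ecgtl_classifier"
  m
}

# --- input-channel adaptation ------------------------------------------------

#' Adapt first-layer convolution weights to a new channel count
#'
#' Duplicates the filters learned on a single input channel across each new
#' channel and rescales the whole layer by the ratio of original to adjusted
#' input channels (1/new). A single-lead signal replicated across all new
#' channels then produces exactly the original layer output.
#'
#' @param w weight matrix (out_channels, k) of a 1-channel convolution
#' @param new_in_channels target channel count (>= 1)
#' @return weight matrix (out_channels, new_in_channels * k)
#' @export
adapt_conv_weights <- function(w, new_in_channels) {
  new_in_channels <- as.integer(new_in_channels)
  if (new_in_channels < 1L) stop("new_in_channels must be >= 1")
  k <- ncol(w)
  wn <- matrix(0, nrow(w), new_in_channels * k)
  for (tap in seq_len(k)) {
    cols <- (tap - 1L) * new_in_channels + seq_len(new_in_channels)
    wn[, cols] <- w[, tap] / new_in_channels
  }
  wn
}

#' Adapt an encoder pretrained on single-lead input to multi-lead input
#'
#' @param enc an encoder with `in_channels = 1`
#' @param new_in_channels target lead count
#' @return the encoder, mutated in place
#' @export
adapt_input_channels <- function(enc, new_in_channels) {
  stopifnot(inherits(enc, "ecgtl_encoder"))
  if (enc$spec$in_channels != 1L) stop("encoder must have a single input channel")
  new_in_channels <- as.integer(new_in_channels)
  if (new_in_channels < 1L) stop("new_in_channels must be >= 1")
  w <- enc$stem$par$w
  enc$stem$par$w <- adapt_conv_weights(w, new_in_channels)
  enc$stem$grad$w <- enc$stem$par$w * 0
  enc$stem$hyper$in_ch <- new_in_channels
  enc$spec$in_channels <- new_in_channels
  invisible(enc)
}

# --- checkpoint state --------------------------------------------------------

encoder_state <- function(enc) {
  list(spec = enc$spec, layers = lapply(encoder_layers(enc), layer_state))
}

encoder_load_state <- function(enc, st) {
  ls <- encoder_layers(enc)
  stopifnot(length(ls) == length(st$layers))
  for (i in seq_along(ls)) layer_load_state(ls[[i]], st$layers[[i]])
  invisible(enc)
}

model_state <- function(m) {
  list(spec = m$spec, activation = m$activation,
       layers = lapply(model_layers(m), layer_state))
}

model_load_state <- function(m, st) {
  ls <- model_layers(m)
  stopifnot(length(ls) == length(st$layers))
  for (i in seq_along(ls)) layer_load_state(ls[[i]], st$layers[[i]])
  invisible(m)
}

# Copy stem + residual-block weights of the stages two encoders share
# (used when a truncated pretrained encoder initializes a full one; the
# stages the pretrained encoder lacks keep their fresh initialization).
init_encoder_from <- function(enc_new, enc_old) {
  layer_load_state(enc_new$stem, layer_state(enc_old$stem))
  shared <- min(enc_new$spec$stages_used, enc_old$spec$stages_used)
  bn <- Filter(function(b) b$stage <= shared, enc_new$blocks)
  bo <- Filter(function(b) b$stage <= shared, enc_old$blocks)
  stopifnot(length(bn) == length(bo))
  for (i in seq_along(bn)) {
    ln <- block_layers(bn[[i]]); lo <- block_layers(bo[[i]])
    for (j in seq_along(ln)) layer_load_state(ln[[j]], layer_state(lo[[j]]))
  }
  if (enc_new$out_dim == enc_old$out_dim)
    layer_load_state(enc_new$bn_final, layer_state(enc_old$bn_final))
  invisible(enc_new)
}
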