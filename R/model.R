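#' Configuration of the dual-branch convolution + transformer network
#'
#' Describes the architecture: an electrode-sequence branch (FE-E) and a
#' time-sequence branch (FE-T), each a convolutional front-end feeding a
#' transformer encoder layer, fused by concatenation into a two-layer
#' classifier. The defaults reproduce the reference shape chain on
#' canonical `(2, 64)` epochs: FE-E widths 64 -> 32 -> 8 -> 1, FE-T widths
#' 64 -> 32 -> 2, token maps `(2, 64)` from both branches, fused flatten
#' width 256.
#'
#' @param n_channels input electrode channels (2).
#' @param n_samples input samples per channel (64).
#' @param conv_filters convolution filters per conv layer; also the token
#'   feature width, so it must equal `d_model`.
#' @param fe_e_kernel1,fe_e_pool1,fe_e_kernel2 FE-E kernel/pool sizes as
#'   `(height, width)` pairs.
#' @param fe_t_kernel,fe_t_pool FE-T kernel/pool sizes.
#' @param d_model transformer token width (64), divisible by `n_heads`.
#' @param n_heads attention heads (4).
#' @param ffn_dim encoder feed-forward width (4 x `d_model` by default).
#' @param dropout_rate dropout after each fully-connected classifier layer,
#'   active only in training mode.
#' @param n_classes output classes (binary: 0 = correct, 1 = error).
#' @return an object of class `model_config`.
#' @export
model_config <- function(n_channels = 2, n_samples = 64, conv_filters = 64,
                         fe_e_kernel1 = c(1, 33), fe_e_pool1 = c(1, 4),
                         fe_e_kernel2 = c(1, 8),
                         fe_t_kernel = c(2, 33), fe_t_pool = c(1, 16),
                         d_model = 64, n_heads = 4, ffn_dim = 4 * d_model,
                         dropout_rate = 0.5, n_classes = 2) {
  cfg <- structure(
    list(n_channels = as.integer(n_channels), n_samples = as.integer(n_samples),
         conv_filters = as.integer(conv_filters),
         fe_e_kernel1 = as.integer(fe_e_kernel1), fe_e_pool1 = as.integer(fe_e_pool1),
         fe_e_kernel2 = as.integer(fe_e_kernel2),
         fe_t_kernel = as.integer(fe_t_kernel), fe_t_pool = as.integer(fe_t_pool),
         d_model = as.integer(d_model), n_heads = as.integer(n_heads),
         ffn_dim = as.integer(ffn_dim), dropout_rate = dropout_rate,
         n_classes = as.integer(n_classes)),
    class = "model_config"
  )
  validate_model_config(cfg)
}

validate_model_config <- function(cfg) {
  w1 <- cfg$n_samples - cfg$fe_e_kernel1[2] + 1L
  if (w1 < 1) stopf("FE-E kernel 1 wider than the input")
  if (w1 %% cfg$fe_e_pool1[2] != 0) {
    stopf("FE-E conv1 output width %d not divisible by pool width %d",
          w1, cfg$fe_e_pool1[2])
  }
  w2 <- w1 %/% cfg$fe_e_pool1[2]
  w3 <- w2 - cfg$fe_e_kernel2[2] + 1L
  if (w3 != 1) {
    stopf("FE-E conv2 must reduce the temporal width to 1 (got %d)", w3)
  }
  tw1 <- cfg$n_samples - cfg$fe_t_kernel[2] + 1L
  if (cfg$fe_t_kernel[1] != cfg$n_channels) {
    stopf("FE-T kernel height must collapse the electrode axis")
  }
  if (tw1 %% cfg$fe_t_pool[2] != 0) {
    stopf("FE-T conv output width %d not divisible by pool width %d",
          tw1, cfg$fe_t_pool[2])
  }
  if (tw1 %/% cfg$fe_t_pool[2] != cfg$n_channels) {
    stopf("FE-T pooling must downsample time positions to the channel count")
  }
  if (cfg$conv_filters != cfg$d_model) {
    stopf("conv_filters must equal d_model (token features are filter outputs)")
  }
  if (cfg$d_model %% cfg$n_heads != 0) stopf("d_model must be divisible by n_heads")
  if (cfg$dropout_rate < 0 || cfg$dropout_rate >= 1) stopf("dropout_rate in [0, 1)")
  cfg
}

#' Build the network with deterministic initialization
#'
#' Weight tensors are drawn Glorot-uniform in a fixed order under the given
#' seed, so two builds with the same configuration and seed are identical.
#'
#' @param config a [model_config()].
#' @param seed integer seed for the initial weights.
#' @return an object of class `errp_network` holding the parameter tree,
#'   the batch-norm running statistics and the configuration.
#' @export
build_network <- function(config = model_config(), seed = 1L) {
  validate_model_config(config)
  with_seed(seed, {
    fused_width <- 2L * config$n_channels * config$d_model
    params <- list(
      fe_e = list(
        conv1 = conv2d_init(1L, config$conv_filters,
                            config$fe_e_kernel1[1], config$fe_e_kernel1[2]),
        bn1 = batchnorm_init(config$conv_filters),
        conv2 = conv2d_init(config$conv_filters, config$conv_filters,
                            config$fe_e_kernel2[1], config$fe_e_kernel2[2]),
        bn2 = batchnorm_init(config$conv_filters),
        enc = encoder_init(config$d_model, config$ffn_dim),
        ln = layernorm_init(config$d_model)
      ),
      fe_t = list(
        conv1 = conv2d_init(1L, config$conv_filters,
                            config$fe_t_kernel[1], config$fe_t_kernel[2]),
        bn1 = batchnorm_init(config$conv_filters),
        enc = encoder_init(config$d_model, config$ffn_dim),
        ln = layernorm_init(config$d_model)
      ),
      fc1 = dense_init(fused_width, config$d_model),
      fc2 = dense_init(config$d_model, config$n_classes)
    )
    state <- list(
      fe_e_bn1 = batchnorm_state_init(config$conv_filters),
      fe_e_bn2 = batchnorm_state_init(config$conv_filters),
      fe_t_bn1 = batchnorm_state_init(config$conv_filters)
    )
    structure(list(config = config, params = params, state = state, seed = seed),
              class = "errp_network")
  })
}

#' @export
print.errp_network <- function(x, ...) {
  cat(sprintf(
    "<errp_network> dual-branch conv+transformer | %d trainable parameters\n",
    count_parameters(x)
  ))
  cat(sprintf("  input (%d, %d) | d_model %d | heads %d | ffn %d | dropout %.2f\n",
              x$config$n_channels, x$config$n_samples, x$config$d_model,
              x$config$n_heads, x$config$ffn_dim, x$config$dropout_rate))
  invisible(x)
}

#' Count trainable parameters
#'
#' @param network an `errp_network`.
#' @return integer total of trainable scalars (batch-norm running
#'   statistics excluded).
#' @export
count_parameters <- function(network) {
  as.integer(tree_sum(length, network$params))
}

## canonicalize input to (B, 1, n_channels, n_samples)
as_model_input <- function(x, config) {
  d <- dim(x)
  if (length(d) == 3L && d[2] == config$n_channels && d[3] == config$n_samples) {
    dim(x) <- c(d[1], 1L, d[2], d[3])
    return(x)
  }
  if (length(d) == 4L && d[2] == 1L && d[3] == config$n_channels &&
      d[4] == config$n_samples) {
    return(x)
  }
  stopf("input must be (B, %d, %d) or (B, 1, %d, %d)",
        config$n_channels, config$n_samples, config$n_channels, config$n_samples)
}

## FE-E branch: conv(1,k1) -> BN -> ReLU -> pool -> conv(1,k2) -> BN ->
## ReLU -> electrode tokens -> encoder -> outer residual -> layernorm
fe_e_forward <- function(params, state, x, config, training, trace = NULL) {
  c1 <- conv2d_forward(params$conv1, x)
  if (!is.null(trace)) trace$fe_e_conv1 <- dim(c1$out)
  b1 <- batchnorm_forward(params$bn1, state$fe_e_bn1, c1$out, training)
  state$fe_e_bn1 <- b1$state
  r1 <- relu_forward(b1$out)
  p1 <- avgpool_forward(r1$out, config$fe_e_pool1[2])
  if (!is.null(trace)) trace$fe_e_pool <- dim(p1$out)
  c2 <- conv2d_forward(params$conv2, p1$out)
  if (!is.null(trace)) trace$fe_e_conv2 <- dim(c2$out)
  b2 <- batchnorm_forward(params$bn2, state$fe_e_bn2, c2$out, training)
  state$fe_e_bn2 <- b2$state
  r2 <- relu_forward(b2$out)
  ## (B, D, L, 1) -> electrode tokens (B, L, D)
  d <- dim(r2$out)
  tok <- aperm(array(r2$out, d[1:3]), c(1, 3, 2))
  enc <- encoder_forward(params$enc, tok, config$n_heads)
  res <- tok + enc$out
  ln <- layernorm_forward(params$ln, matrix(res, d[1] * d[3], config$d_model))
  out <- array(ln$out, c(d[1], d[3], config$d_model))
  if (!is.null(trace)) trace$fe_e_encoder <- dim(out)
  list(out = out, state = state, trace = trace,
       cache = list(c1 = c1$cache, b1 = b1$cache, r1 = r1$cache, p1 = p1$cache,
                    c2 = c2$cache, b2 = b2$cache, r2 = r2$cache,
                    enc = enc$cache, ln = ln$cache, d = d))
}

fe_e_backward <- function(params, cache, dout) {
  d <- cache$d
  g_ln <- matrix(dout, d[1] * d[3], length(params$ln$gamma))
  b_ln <- layernorm_backward(params$ln, cache$ln, g_ln)
  d_res <- array(b_ln$dx, c(d[1], d[3], ncol(b_ln$dx)))
  b_enc <- encoder_backward(params$enc, cache$enc, d_res)
  d_tok <- d_res + b_enc$dx
  ## tokens (B, L, D) -> (B, D, L, 1)
  d_r2 <- aperm(d_tok, c(1, 3, 2))
  dim(d_r2) <- c(d[1], d[2], d[3], 1L)
  g <- relu_backward(cache$r2, d_r2)
  b_b2 <- batchnorm_backward(params$bn2, cache$b2, g)
  b_c2 <- conv2d_backward(params$conv2, cache$c2, b_b2$dx)
  g <- avgpool_backward(cache$p1, b_c2$dx)
  g <- relu_backward(cache$r1, g)
  b_b1 <- batchnorm_backward(params$bn1, cache$b1, g)
  b_c1 <- conv2d_backward(params$conv1, cache$c1, b_b1$dx)
  list(dx = b_c1$dx,
       dparams = list(conv1 = b_c1$dparams, bn1 = b_b1$dparams,
                      conv2 = b_c2$dparams, bn2 = b_b2$dparams,
                      enc = b_enc$dparams, ln = b_ln$dparams))
}

## FE-T branch: conv(2,k) collapsing electrodes -> BN -> ReLU -> pool ->
## time tokens -> encoder -> outer residual -> layernorm
fe_t_forward <- function(params, state, x, config, training, trace = NULL) {
  c1 <- conv2d_forward(params$conv1, x)
  if (!is.null(trace)) trace$fe_t_conv1 <- dim(c1$out)
  b1 <- batchnorm_forward(params$bn1, state$fe_t_bn1, c1$out, training)
  state$fe_t_bn1 <- b1$state
  r1 <- relu_forward(b1$out)
  p1 <- avgpool_forward(r1$out, config$fe_t_pool[2])
  if (!is.null(trace)) trace$fe_t_pool <- dim(p1$out)
  ## (B, D, 1, L) -> time tokens (B, L, D)
  d <- dim(p1$out)
  tok <- aperm(array(p1$out, c(d[1], d[2], d[4])), c(1, 3, 2))
  enc <- encoder_forward(params$enc, tok, config$n_heads)
  res <- tok + enc$out
  ln <- layernorm_forward(params$ln, matrix(res, d[1] * d[4], config$d_model))
  out <- array(ln$out, c(d[1], d[4], config$d_model))
  if (!is.null(trace)) trace$fe_t_encoder <- dim(out)
  list(out = out, state = state, trace = trace,
       cache = list(c1 = c1$cache, b1 = b1$cache, r1 = r1$cache, p1 = p1$cache,
                    enc = enc$cache, ln = ln$cache, d = d))
}

fe_t_backward <- function(params, cache, dout) {
  d <- cache$d
  g_ln <- matrix(dout, d[1] * d[4], length(params$ln$gamma))
  b_ln <- layernorm_backward(params$ln, cache$ln, g_ln)
  d_res <- array(b_ln$dx, c(d[1], d[4], ncol(b_ln$dx)))
  b_enc <- encoder_backward(params$enc, cache$enc, d_res)
  d_tok <- d_res + b_enc$dx
  d_p1 <- aperm(d_tok, c(1, 3, 2))
  dim(d_p1) <- d
  g <- avgpool_backward(cache$p1, d_p1)
  g <- relu_backward(cache$r1, g)
  b_b1 <- batchnorm_backward(params$bn1, cache$b1, g)
  b_c1 <- conv2d_backward(params$conv1, cache$c1, b_b1$dx)
  list(dx = b_c1$dx,
       dparams = list(conv1 = b_c1$dparams, bn1 = b_b1$dparams,
                      enc = b_enc$dparams, ln = b_ln$dparams))
}

## row-major flatten of token maps: column (l-1)*D + d
flatten_tokens <- function(tok) {
  d <- dim(tok)
  matrix(aperm(tok, c(1, 3, 2)), d[1], d[2] * d[3])
}

unflatten_tokens <- function(m, L, D) {
  arr <- array(m, c(nrow(m), D, L))
  aperm(arr, c(1, 3, 2))
}

## full forward pass; returns probabilities plus everything needed for
## backprop and shape tracing
network_forward <- function(network, x, training = FALSE, with_trace = FALSE,
                            with_cache = FALSE) {
  config <- network$config
  x <- as_model_input(x, config)
  trace <- if (with_trace) list(input = dim(x)) else NULL
  fe <- fe_e_forward(network$params$fe_e, network$state, x, config, training, trace)
  trace <- fe$trace
  ft <- fe_t_forward(network$params$fe_t, fe$state, x, config, training, trace)
  trace <- ft$trace
  state <- ft$state
  fused <- array(0, c(dim(fe$out)[1], dim(fe$out)[2] + dim(ft$out)[2], config$d_model))
  fused[, seq_len(dim(fe$out)[2]), ] <- fe$out
  fused[, dim(fe$out)[2] + seq_len(dim(ft$out)[2]), ] <- ft$out
  flat <- flatten_tokens(fused)
  if (!is.null(trace)) trace$flatten <- dim(flat)
  f1 <- dense_forward(network$params$fc1, flat)
  if (!is.null(trace)) trace$fc1 <- dim(f1$out)
  dr1 <- dropout_forward(f1$out, config$dropout_rate, training)
  f2 <- dense_forward(network$params$fc2, dr1$out)
  dr2 <- dropout_forward(f2$out, config$dropout_rate, training)
  if (!is.null(trace)) trace$fc2 <- dim(f2$out)
  probs <- softmax_rows(dr2$out)
  out <- list(probs = probs, state = state, trace = trace)
  if (with_cache) {
    out$cache <- list(fe = fe$cache, ft = ft$cache, L_e = dim(fe$out)[2],
                      L_t = dim(ft$out)[2], f1 = f1$cache, dr1 = dr1$cache,
                      f2 = f2$cache, dr2 = dr2$cache, probs = probs)
  }
  out
}

softmax_rows <- function(z) {
  m <- apply(z, 1, max)
  e <- exp(z - m)
  e / rowSums(e)
}

## backward pass from d(logits) through the whole network
network_backward <- function(network, cache, dlogits) {
  config <- network$config
  g <- dropout_backward(cache$dr2, dlogits)
  b_f2 <- dense_backward(network$params$fc2, cache$f2, g)
  g <- dropout_backward(cache$dr1, b_f2$dx)
  b_f1 <- dense_backward(network$params$fc1, cache$f1, g)
  L <- cache$L_e + cache$L_t
  d_fused <- unflatten_tokens(b_f1$dx, L, config$d_model)
  d_fe <- d_fused[, seq_len(cache$L_e), , drop = FALSE]
  d_ft <- d_fused[, cache$L_e + seq_len(cache$L_t), , drop = FALSE]
  b_fe <- fe_e_backward(network$params$fe_e, cache$fe, d_fe)
  b_ft <- fe_t_backward(network$params$fe_t, cache$ft, d_ft)
  list(dparams = list(fe_e = b_fe$dparams, fe_t = b_ft$dparams,
                      fc1 = b_f1$dparams, fc2 = b_f2$dparams),
       dx = b_fe$dx + b_ft$dx)
}

#' Electrode-branch (FE-E) forward pass
#'
#' Treats the epoch as a length-2 sequence of electrode tokens: two
#' convolutions (with batch-norm, ReLU and average pooling between them)
#' reduce each electrode's temporal axis to a single position, the 64
#' filter outputs become the electrode's feature vector, and a transformer
#' encoder layer models the electrode-electrode interaction. The encoder
#' output is combined with its input through an additional residual
#' connection and layer-normalized.
#'
#' @param network an `errp_network`.
#' @param x input epochs, `(B, n_channels, n_samples)` or
#'   `(B, 1, n_channels, n_samples)`.
#' @param training logical; training mode uses batch statistics in the
#'   batch-norm layers.
#' @return a `(B, n_channels, d_model)` token array.
#' @export
forward_fe_e <- function(network, x, training = FALSE) {
  x <- as_model_input(x, network$config)
  fe_e_forward(network$params$fe_e, network$state, x, network$config, training)$out
}

#' Time-branch (FE-T) forward pass
#'
#' Treats the epoch as a sequence of sampling points: a `(2, 33)`
#' convolution collapses the electrode axis, average pooling downsamples
#' the time positions to the channel count, the filter outputs become each
#' time token's features, and a transformer encoder layer models the
#' temporal interaction, followed by the outer residual and layer norm.
#'
#' @inheritParams forward_fe_e
#' @return a `(B, n_channels, d_model)` token array.
#' @export
forward_fe_t <- function(network, x, training = FALSE) {
  x <- as_model_input(x, network$config)
  fe_t_forward(network$params$fe_t, network$state, x, network$config, training)$out
}

#' Full forward pass: class probabilities
#'
#' Concatenates the FE-E and FE-T token maps (FE-E first), flattens to the
#' fused feature vector, applies the two fully-connected layers (dropout
#' active only in training mode) and a softmax. Inference mode is
#' deterministic and batch-composition independent (batch norm uses running
#' statistics).
#'
#' @inheritParams forward_fe_e
#' @param with_trace if `TRUE`, attach the intermediate tensor shapes as
#'   attribute `"trace"` (a named list matching the architecture's shape
#'   chain).
#' @return a `(B, n_classes)` matrix of class probabilities; rows sum to 1.
#'   Column 2 is the error-class probability.
#' @export
#' @examples
#' net <- build_network(model_config(), seed = 1)
#' p <- forward(net, array(rnorm(8 * 2 * 64), c(8, 2, 64)), with_trace = TRUE)
#' attr(p, "trace")$flatten
forward <- function(network, x, training = FALSE, with_trace = FALSE) {
  res <- network_forward(network, x, training = training, with_trace = with_trace)
  probs <- res$probs
  if (with_trace) attr(probs, "trace") <- res$trace
  probs
}

#' Save / load a network checkpoint
#'
#' A checkpoint is a single RDS file holding the full parameter tree, the
#' batch-norm running statistics, the model configuration and the build
#' seed; reloading reproduces inference output bit-exactly.
#'
#' @param network an `errp_network`.
#' @param path checkpoint file path.
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   returns the `errp_network`.
#' @export
save_checkpoint <- function(network, path) {
  stopifnot(inherits(network, "errp_network"))
  saveRDS(unclass(network), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  need <- c("config", "params", "state", "seed")
  if (!is.list(obj) || !all(need %in% names(obj))) {
    stopf("%s is not an errp_network checkpoint", path)
  }
  structure(obj[need], class = "errp_network")
}
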