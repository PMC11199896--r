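## Minimal neural-network layer kit: each layer exposes a forward pass
## returning (out, cache) and a backward pass returning (dx, dparams).
## Tensors are plain R arrays in (batch, channel, height, width) layout;
## convolutions are im2col + BLAS matrix multiplies, which is fast at the
## (2 x 64) epoch sizes this package works with.

## ---- initialization ---------------------------------------------------

glorot_uniform <- function(dims, fan_in, fan_out) {
  limit <- sqrt(6 / (fan_in + fan_out))
  array(runif(prod(dims), -limit, limit), dims)
}

## ---- im2col index maps ------------------------------------------------

## linear indices into an array of dim (B, C_in, H, W) arranged as a
## (B*H_out*W_out) x (C_in*kh*kw) gather map for a valid convolution;
## memoised because the same shapes recur for every minibatch
.conv_idx_cache <- new.env(parent = emptyenv())

conv_gather_idx <- function(B, C_in, H, W, kh, kw) {
  key <- paste(B, C_in, H, W, kh, kw, sep = "x")
  hit <- .conv_idx_cache[[key]]
  if (!is.null(hit)) return(hit)
  H_out <- H - kh + 1L
  W_out <- W - kw + 1L
  base <- outer(seq_len(B), (seq_len(H_out) - 1L) * B * C_in, "+")
  base <- as.vector(outer(as.vector(base), (seq_len(W_out) - 1L) * B * C_in * H, "+"))
  off <- outer((seq_len(C_in) - 1L) * B, (seq_len(kh) - 1L) * B * C_in, "+")
  off <- as.vector(outer(as.vector(off), (seq_len(kw) - 1L) * B * C_in * H, "+"))
  idx <- outer(base, off, "+")
  storage.mode(idx) <- "integer"
  res <- list(idx = idx, H_out = H_out, W_out = W_out)
  if (length(.conv_idx_cache) < 64) .conv_idx_cache[[key]] <- res
  res
}

## ---- conv2d (valid padding, stride 1) ---------------------------------

## weights stored as (C_in, kh, kw, C_out) so matrix(W, K, C_out) matches
## the gather-column order (ci fastest, then dh, then dw)
conv2d_init <- function(C_in, C_out, kh, kw) {
  fan_in <- C_in * kh * kw
  list(W = glorot_uniform(c(C_in, kh, kw, C_out), fan_in, C_out),
       b = numeric(C_out))
}

conv2d_forward <- function(params, x) {
  d <- dim(x)
  wd <- dim(params$W)
  g <- conv_gather_idx(d[1], d[2], d[3], d[4], wd[2], wd[3])
  Wm <- matrix(params$W, ncol = wd[4])
  res <- .conv_fwd_cpp(x, g$idx, Wm, params$b, d[1], g$H_out, g$W_out)
  list(out = res$out, cache = list(M = res$M, idx = g$idx, x_dim = d,
                                   w_dim = wd, Wm = Wm,
                                   H_out = g$H_out, W_out = g$W_out))
}

conv2d_backward <- function(params, cache, dout) {
  wd <- cache$w_dim
  res <- .conv_bwd_cpp(dout, cache$M, cache$idx, cache$Wm,
                       prod(cache$x_dim), cache$x_dim[1],
                       cache$H_out, cache$W_out)
  dx <- res$dx
  dim(dx) <- cache$x_dim
  list(dx = dx, dparams = list(W = array(res$dW, wd), b = res$db))
}

## ---- batch normalization over (B, H, W) per channel -------------------

batchnorm_init <- function(C) {
  list(gamma = rep(1, C), beta = numeric(C))
}

batchnorm_state_init <- function(C) {
  list(mean = numeric(C), var = rep(1, C))
}

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

batchnorm_forward <- function(params, state, x, training) {
  d <- dim(x)
  res <- .bn_fwd_cpp(x, d[1], d[2], d[3] * d[4], params$gamma, params$beta,
                     state$mean, state$var, training, BN_EPS, BN_MOMENTUM)
  if (training) {
    state$mean <- res$mean
    state$var <- res$var
  }
  out <- res$out
  dim(out) <- d
  list(out = out, state = state,
       cache = list(xhat = res$xhat, inv_sd = res$inv_sd, d = d,
                    training = training))
}

batchnorm_backward <- function(params, cache, dout) {
  d <- cache$d
  res <- .bn_bwd_cpp(dout, cache$xhat, cache$inv_sd, params$gamma,
                     d[1], d[2], d[3] * d[4], cache$training)
  dx <- res$dx
  dim(dx) <- d
  list(dx = dx, dparams = list(gamma = res$dgamma, beta = res$dbeta))
}

## ---- relu -------------------------------------------------------------

relu_forward <- function(x) {
  mask <- x > 0
  list(out = x * mask, cache = mask)
}

relu_backward <- function(cache, dout) dout * cache

## ---- average pooling (1, p), stride p ---------------------------------

## block-averaging matrix (p*W_out, W_out); BLAS does the pooling
pool_matrix <- function(p, W_out) {
  S <- matrix(0, p * W_out, W_out)
  S[cbind(seq_len(p * W_out), rep(seq_len(W_out), each = p))] <- 1 / p
  S
}

avgpool_forward <- function(x, p) {
  d <- dim(x)
  stopifnot(d[4] %% p == 0)
  W_out <- d[4] %/% p
  m <- x
  dim(m) <- c(d[1] * d[2] * d[3], d[4])
  S <- pool_matrix(p, W_out)
  out <- m %*% S
  dim(out) <- c(d[1], d[2], d[3], W_out)
  list(out = out, cache = list(d = d, p = p, S = S))
}

avgpool_backward <- function(cache, dout) {
  d <- cache$d
  g <- dout
  dim(g) <- c(d[1] * d[2] * d[3], d[4] %/% cache$p)
  dx <- tcrossprod(g, cache$S)
  dim(dx) <- d
  dx
}

## ---- dense ------------------------------------------------------------

dense_init <- function(n_in, n_out) {
  list(W = glorot_uniform(c(n_in, n_out), n_in, n_out), b = numeric(n_out))
}

dense_forward <- function(params, x) {
  y <- x %*% params$W
  y <- y + rep(params$b, each = nrow(y))
  list(out = y, cache = x)
}

dense_backward <- function(params, cache, dout) {
  list(dx = tcrossprod(dout, params$W),
       dparams = list(W = crossprod(cache, dout), b = colSums(dout)))
}

## ---- dropout ----------------------------------------------------------

dropout_forward <- function(x, rate, training) {
  if (!training || rate <= 0) {
    return(list(out = x, cache = NULL))
  }
  mask <- (runif(length(x)) >= rate) / (1 - rate)
  dim(mask) <- dim(x)
  list(out = x * mask, cache = mask)
}

dropout_backward <- function(cache, dout) {
  if (is.null(cache)) dout else dout * cache
}

## ---- layer normalization over the feature axis ------------------------

layernorm_init <- function(D) list(gamma = rep(1, D), beta = numeric(D))

LN_EPS <- 1e-5

## x: (R, D) matrix of token feature vectors
layernorm_forward <- function(params, x) {
  D <- ncol(x)
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc^2)
  inv_sd <- 1 / sqrt(v + LN_EPS)
  xhat <- xc * inv_sd
  y <- xhat * rep(params$gamma, each = nrow(x)) + rep(params$beta, each = nrow(x))
  list(out = y, cache = list(xhat = xhat, inv_sd = inv_sd))
}

layernorm_backward <- function(params, cache, dout) {
  n <- nrow(dout)
  dgamma <- colSums(dout * cache$xhat)
  dbeta <- colSums(dout)
  dxhat <- dout * rep(params$gamma, each = n)
  dx <- cache$inv_sd *
    (dxhat - rowMeans(dxhat) - cache$xhat * rowMeans(dxhat * cache$xhat))
  list(dx = dx, dparams = list(gamma = dgamma, beta = dbeta))
}

## ---- multi-head self-attention ----------------------------------------

mha_init <- function(D) {
  list(Wq = glorot_uniform(c(D, D), D, D), bq = numeric(D),
       Wk = glorot_uniform(c(D, D), D, D), bk = numeric(D),
       Wv = glorot_uniform(c(D, D), D, D), bv = numeric(D),
       Wo = glorot_uniform(c(D, D), D, D), bo = numeric(D))
}

## sum a (B, h, dk) array over its last axis -> (B, h) matrix
sum_last <- function(P) {
  d <- dim(P)
  dim(P) <- c(d[1] * d[2], d[3])
  v <- rowSums(P)
  dim(v) <- d[1:2]
  v
}

## broadcast a (B, h) matrix along a new trailing dk axis -> (B, h, dk)
bcast_last <- function(m, dk) array(rep(m, times = dk), c(dim(m), dk))

## x: (B, L, D) token array -> (B, L, D)
mha_forward <- function(params, x, n_heads) {
  d <- dim(x)
  B <- d[1]; L <- d[2]; D <- d[3]
  dk <- D %/% n_heads
  xm <- matrix(x, B * L, D)
  qm <- xm %*% params$Wq + rep(params$bq, each = B * L)
  km <- xm %*% params$Wk + rep(params$bk, each = B * L)
  vm <- xm %*% params$Wv + rep(params$bv, each = B * L)
  ## (B, L, h, dk) views
  Q <- array(qm, c(B, L, n_heads, dk))
  K <- array(km, c(B, L, n_heads, dk))
  V <- array(vm, c(B, L, n_heads, dk))
  scale <- 1 / sqrt(dk)
  ## token slice helpers: cheap reshape instead of array() copies
  tok_slice <- function(a, l) {
    x <- a[, l, , , drop = FALSE]
    dim(x) <- c(B, n_heads, dk)
    x
  }
  pair_slice <- function(a, l1, l2) {
    x <- a[, l1, l2, , drop = FALSE]
    dim(x) <- c(B, n_heads)
    x
  }
  ## scores S[b, l1, l2, h]
  S <- array(0, c(B, L, L, n_heads))
  for (l1 in seq_len(L)) for (l2 in seq_len(L)) {
    S[, l1, l2, ] <- sum_last(tok_slice(Q, l1) * tok_slice(K, l2)) * scale
  }
  ## softmax over l2, numerically stabilized per (b, l1, h)
  A <- S
  for (l1 in seq_len(L)) {
    mx <- pair_slice(S, l1, 1)
    if (L > 1) for (l2 in 2:L) mx <- pmax(mx, pair_slice(S, l1, l2))
    ex <- vector("list", L)
    tot <- 0
    for (l2 in seq_len(L)) {
      ex[[l2]] <- exp(pair_slice(S, l1, l2) - mx)
      tot <- tot + ex[[l2]]
    }
    for (l2 in seq_len(L)) A[, l1, l2, ] <- ex[[l2]] / tot
  }
  ## context Ctx[b, l1, h, dk] = sum_l2 A[b, l1, l2, h] V[b, l2, h, dk]
  Ctx <- array(0, c(B, L, n_heads, dk))
  for (l1 in seq_len(L)) {
    acc <- 0
    for (l2 in seq_len(L)) {
      acc <- acc + tok_slice(V, l2) * bcast_last(pair_slice(A, l1, l2), dk)
    }
    Ctx[, l1, , ] <- acc
  }
  cm <- matrix(Ctx, B * L, D)
  y <- cm %*% params$Wo + rep(params$bo, each = B * L)
  out <- array(y, c(B, L, D))
  list(out = out,
       cache = list(xm = xm, Q = Q, K = K, V = V, A = A, cm = cm,
                    B = B, L = L, D = D, n_heads = n_heads, dk = dk, scale = scale))
}

mha_backward <- function(params, cache, dout) {
  B <- cache$B; L <- cache$L; D <- cache$D
  h <- cache$n_heads; dk <- cache$dk
  dy <- matrix(dout, B * L, D)
  dWo <- crossprod(cache$cm, dy)
  dbo <- colSums(dy)
  dcm <- tcrossprod(dy, params$Wo)
  dCtx <- array(dcm, c(B, L, h, dk))
  tok_slice <- function(a, l) {
    x <- a[, l, , , drop = FALSE]
    dim(x) <- c(B, h, dk)
    x
  }
  pair_slice <- function(a, l1, l2) {
    x <- a[, l1, l2, , drop = FALSE]
    dim(x) <- c(B, h)
    x
  }
  dA <- array(0, c(B, L, L, h))
  dV <- array(0, c(B, L, h, dk))
  for (l2 in seq_len(L)) {
    accV <- 0
    for (l1 in seq_len(L)) {
      dC1 <- tok_slice(dCtx, l1)
      dA[, l1, l2, ] <- sum_last(dC1 * tok_slice(cache$V, l2))
      accV <- accV + dC1 * bcast_last(pair_slice(cache$A, l1, l2), dk)
    }
    dV[, l2, , ] <- accV
  }
  ## softmax jacobian: dS = A * (dA - sum_l2 dA * A)
  dS <- array(0, c(B, L, L, h))
  for (l1 in seq_len(L)) {
    inner <- 0
    for (l2 in seq_len(L)) {
      inner <- inner + pair_slice(dA, l1, l2) * pair_slice(cache$A, l1, l2)
    }
    for (l2 in seq_len(L)) {
      dS[, l1, l2, ] <- pair_slice(cache$A, l1, l2) * (pair_slice(dA, l1, l2) - inner)
    }
  }
  dQ <- array(0, c(B, L, h, dk))
  dK <- array(0, c(B, L, h, dk))
  for (l1 in seq_len(L)) {
    accQ <- 0
    for (l2 in seq_len(L)) {
      w <- bcast_last(pair_slice(dS, l1, l2), dk) * cache$scale
      accQ <- accQ + w * tok_slice(cache$K, l2)
      dK[, l2, , ] <- tok_slice(dK, l2) + w * tok_slice(cache$Q, l1)
    }
    dQ[, l1, , ] <- accQ
  }
  dqm <- matrix(dQ, B * L, D)
  dkm <- matrix(dK, B * L, D)
  dvm <- matrix(dV, B * L, D)
  dx <- tcrossprod(dqm, params$Wq) + tcrossprod(dkm, params$Wk) + tcrossprod(dvm, params$Wv)
  dparams <- list(
    Wq = crossprod(cache$xm, dqm), bq = colSums(dqm),
    Wk = crossprod(cache$xm, dkm), bk = colSums(dkm),
    Wv = crossprod(cache$xm, dvm), bv = colSums(dvm),
    Wo = dWo, bo = dbo
  )
  list(dx = array(dx, c(B, L, D)), dparams = dparams)
}

## ---- transformer encoder layer (post-norm) ----------------------------

encoder_init <- function(D, ffn_dim) {
  list(attn = mha_init(D),
       ln1 = layernorm_init(D),
       ffn1 = dense_init(D, ffn_dim),
       ffn2 = dense_init(ffn_dim, D),
       ln2 = layernorm_init(D))
}

## x: (B, L, D); post-norm: LN(x + MHA(x)) then LN( . + FFN(.))
encoder_forward <- function(params, x, n_heads) {
  d <- dim(x)
  att <- mha_forward(params$attn, x, n_heads)
  r1 <- matrix(x + att$out, d[1] * d[2], d[3])
  ln1 <- layernorm_forward(params$ln1, r1)
  f1 <- dense_forward(params$ffn1, ln1$out)
  rl <- relu_forward(f1$out)
  f2 <- dense_forward(params$ffn2, rl$out)
  r2 <- ln1$out + f2$out
  ln2 <- layernorm_forward(params$ln2, r2)
  out <- array(ln2$out, d)
  list(out = out,
       cache = list(att = att$cache, ln1 = ln1$cache, f1 = f1$cache,
                    rl = rl$cache, f2 = f2$cache, ln2 = ln2$cache, d = d))
}

encoder_backward <- function(params, cache, dout) {
  d <- cache$d
  g <- matrix(dout, d[1] * d[2], d[3])
  b_ln2 <- layernorm_backward(params$ln2, cache$ln2, g)
  b_f2 <- dense_backward(params$ffn2, cache$f2, b_ln2$dx)
  b_rl <- relu_backward(cache$rl, b_f2$dx)
  b_f1 <- dense_backward(params$ffn1, cache$f1, b_rl)
  d_ln1_out <- b_ln2$dx + b_f1$dx
  b_ln1 <- layernorm_backward(params$ln1, cache$ln1, d_ln1_out)
  d_r1 <- array(b_ln1$dx, d)
  b_att <- mha_backward(params$attn, cache$att, d_r1)
  dx <- d_r1 + b_att$dx
  list(dx = dx,
       dparams = list(attn = b_att$dparams, ln1 = b_ln1$dparams,
                      ffn1 = b_f1$dparams, ffn2 = b_f2$dparams,
                      ln2 = b_ln2$dparams))
}

## ---- parameter-tree helpers -------------------------------------------

tree_map <- function(f, tree) {
  if (is.list(tree)) {
    out <- lapply(tree, function(el) tree_map(f, el))
    names(out) <- names(tree)
    out
  } else {
    f(tree)
  }
}

tree_map2 <- function(f, a, b) {
  if (is.list(a)) {
    for (i in seq_along(a)) a[[i]] <- tree_map2(f, a[[i]], b[[i]])
    a
  } else {
    f(a, b)
  }
}

tree_sum <- function(f, tree) {
  if (is.list(tree)) {
    sum(vapply(tree, function(el) tree_sum(f, el), numeric(1)))
  } else {
    f(tree)
  }
}
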