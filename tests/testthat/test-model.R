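test_that("the traced forward pass reproduces the architecture's shape chain", {
  net <- build_network(model_config(), seed = 1)
  x <- array(rnorm(8 * 2 * 64), c(8, 2, 64))
  p <- forward(net, x, with_trace = TRUE)
  tr <- attr(p, "trace")
  expect_equal(tr$input, c(8, 1, 2, 64))
  expect_equal(tr$fe_e_conv1, c(8, 64, 2, 32))
  expect_equal(tr$fe_e_pool, c(8, 64, 2, 8))
  expect_equal(tr$fe_e_conv2, c(8, 64, 2, 1))
  expect_equal(tr$fe_e_encoder, c(8, 2, 64))
  expect_equal(tr$fe_t_conv1, c(8, 64, 1, 32))
  expect_equal(tr$fe_t_pool, c(8, 64, 1, 2))
  expect_equal(tr$fe_t_encoder, c(8, 2, 64))
  expect_equal(tr$flatten, c(8, 256))
  expect_equal(tr$fc1, c(8, 64))
  expect_equal(tr$fc2, c(8, 2))
})

test_that("softmax output is a valid probability matrix and inference is stable", {
  net <- build_network(model_config(), seed = 2)
  x <- array(rnorm(5 * 2 * 64), c(5, 2, 64))
  p1 <- forward(net, x)
  p2 <- forward(net, x)
  expect_equal(dim(p1), c(5, 2))
  expect_true(all(p1 >= 0 & p1 <= 1))
  expect_equal(rowSums(p1), rep(1, 5), tolerance = 1e-6)
  expect_identical(p1, p2) # dropout inactive at inference

  ## batch-composition independence in inference mode
  single <- forward(net, x[2, , , drop = FALSE])
  expect_equal(as.numeric(single), as.numeric(p1[2, ]), tolerance = 1e-12)
})

test_that("weight initialization is deterministic given the seed", {
  a <- build_network(model_config(), seed = 7)
  b <- build_network(model_config(), seed = 7)
  c <- build_network(model_config(), seed = 8)
  expect_identical(a$params, b$params)
  expect_false(identical(a$params$fc1$W, c$params$fc1$W))
})

test_that("parameter counting is stable, monotone and matches closed form", {
  cfg <- model_config()
  n1 <- count_parameters(build_network(cfg, 1))
  n2 <- count_parameters(build_network(cfg, 99))
  expect_identical(n1, n2)

  ## independent per-layer arithmetic from the configuration
  conv_n <- function(cin, kh, kw, cout) cin * kh * kw * cout + cout
  bn_n <- function(c) 2 * c
  ln_n <- function(d) 2 * d
  enc_n <- function(d, f) 4 * (d * d + d) + (d * f + f) + (f * d + d) + 2 * ln_n(d)
  expected <- conv_n(1, 1, 33, 64) + bn_n(64) +
    conv_n(64, 1, 8, 64) + bn_n(64) + enc_n(64, 256) + ln_n(64) +
    conv_n(1, 2, 33, 64) + bn_n(64) + enc_n(64, 256) + ln_n(64) +
    (256 * 64 + 64) + (64 * 2 + 2)
  expect_identical(n1, as.integer(expected))

  bigger <- model_config(conv_filters = 128, d_model = 128)
  expect_gt(count_parameters(build_network(bigger, 1)), n1)
})

test_that("inconsistent configurations are rejected at build time", {
  expect_error(model_config(fe_e_pool1 = c(1, 5)), "not divisible")
  expect_error(model_config(fe_e_kernel2 = c(1, 4)), "reduce the temporal width")
  expect_error(model_config(n_heads = 5), "divisible by n_heads")
  expect_error(model_config(conv_filters = 32), "equal d_model")
  expect_error(model_config(fe_t_kernel = c(1, 33)), "collapse the electrode")
})

test_that("the convolution primitive matches a hand-computed oracle", {
  set.seed(9)
  x <- array(sample(-5:5, 2 * 64, replace = TRUE), c(1, 1, 2, 64))
  params <- list(W = array(rnorm(1 * 2 * 33 * 1), c(1, 2, 33, 1)), b = 0.3)
  out <- conv2d_forward(params, x)$out
  expect_equal(dim(out), c(1, 1, 1, 32))
  ## direct double-loop convolution
  for (wo in c(1, 7, 32)) {
    acc <- 0.3
    for (dh in 1:2) for (dw in 1:33) {
      acc <- acc + x[1, 1, dh, wo + dw - 1] * params$W[1, dh, dw, 1]
    }
    expect_equal(out[1, 1, 1, wo], acc, tolerance = 1e-12)
  }
  ## swapping input channels is equivalent to swapping kernel rows
  xs <- x[, , 2:1, , drop = FALSE]
  ps <- params
  ps$W <- params$W[, 2:1, , , drop = FALSE]
  expect_equal(conv2d_forward(ps, xs)$out, out, tolerance = 1e-12)
})

test_that("zeroed encoder weights reduce a branch to layernorm of its input", {
  net <- build_network(model_config(dropout_rate = 0), seed = 3)
  net$params$fe_e$enc <- tree_map(function(p) p * 0, net$params$fe_e$enc)
  x <- array(rnorm(4 * 2 * 64), c(4, 2, 64))
  out <- forward_fe_e(net, x)

  ## manual composition of the convolutional front-end
  xin <- x
  dim(xin) <- c(4, 1, 2, 64)
  c1 <- conv2d_forward(net$params$fe_e$conv1, xin)
  b1 <- batchnorm_forward(net$params$fe_e$bn1, net$state$fe_e_bn1, c1$out, FALSE)
  r1 <- relu_forward(b1$out)
  p1 <- avgpool_forward(r1$out, 4)
  c2 <- conv2d_forward(net$params$fe_e$conv2, p1$out)
  b2 <- batchnorm_forward(net$params$fe_e$bn2, net$state$fe_e_bn2, c2$out, FALSE)
  r2 <- relu_forward(b2$out)
  tok <- aperm(array(r2$out, c(4, 64, 2)), c(1, 3, 2))
  ln <- layernorm_forward(net$params$fe_e$ln, matrix(tok, 8, 64))
  expect_equal(out, array(ln$out, c(4, 2, 64)), tolerance = 1e-12)
})

test_that("analytic gradients match finite differences on sampled weights", {
  set.seed(13)
  net <- build_network(model_config(dropout_rate = 0), seed = 5)
  x <- array(rnorm(3 * 2 * 64) * 0.5, c(3, 2, 64))
  y <- c(1L, 0L, 1L)
  loss_of <- function(n) {
    fwd <- network_forward(n, x, training = TRUE, with_cache = TRUE)
    tg <- smooth_targets(y, 2, 0.1)
    -mean(rowSums(tg * log(pmax(fwd$probs, 1e-12))))
  }
  fwd <- network_forward(net, x, training = TRUE, with_cache = TRUE)
  tg <- smooth_targets(y, 2, 0.1)
  grads <- network_backward(net, fwd$cache, (fwd$probs - tg) / 3)$dparams

  probe <- list(c("fc2", "W"), c("fc1", "W"), c("fe_e", "conv1", "W"),
                c("fe_t", "conv1", "W"), c("fe_e", "enc", "attn", "Wq"),
                c("fe_e", "enc", "ffn1", "W"), c("fe_t", "ln", "gamma"),
                c("fe_e", "bn1", "gamma"))
  eps <- 1e-6 # small enough that central differences rarely cross a kink
  for (path in probe) {
    leaf <- purrr::pluck(net$params, !!!path)
    i <- sample(length(leaf), 1)
    g_ana <- purrr::pluck(grads, !!!path)[i]
    np <- net
    purrr::pluck(np$params, !!!path)[i] <- leaf[i] + eps
    fp <- loss_of(np)
    purrr::pluck(np$params, !!!path)[i] <- leaf[i] - eps
    fm <- loss_of(np)
    g_num <- (fp - fm) / (2 * eps)
    ## central differences cross ReLU kinks, so allow a small slack and
    ## skip coordinates whose gradient is numerically zero
    if (abs(g_ana) < 1e-10 && abs(g_num) < 1e-7) next
    rel <- abs(g_ana - g_num) / max(1e-8, abs(g_ana) + abs(g_num))
    expect_lt(rel, 2e-3, label = paste(c(path, i, "rel"), collapse = "/"))
  }
})

test_that("gradient reaches every branch after one training step", {
  net <- build_network(model_config(dropout_rate = 0), seed = 6)
  x <- array(rnorm(8 * 2 * 64) * 0.3, c(8, 2, 64))
  y <- rep(c(0L, 1L), 4)
  fwd <- network_forward(net, x, training = TRUE, with_cache = TRUE)
  tg <- smooth_targets(y, 2, 0.1)
  grads <- network_backward(net, fwd$cache, (fwd$probs - tg) / 8)$dparams
  norm_of <- function(g) tree_sum(function(v) sum(v^2), g)
  ## every structural block receives gradient (conv biases that feed
  ## straight into batch-norm are analytically zero and not probed)
  expect_gt(norm_of(grads$fe_e$conv1$W), 0)
  expect_gt(norm_of(grads$fe_e$conv2$W), 0)
  expect_gt(norm_of(grads$fe_e$enc), 0)
  expect_gt(norm_of(grads$fe_e$ln), 0)
  expect_gt(norm_of(grads$fe_t$conv1$W), 0)
  expect_gt(norm_of(grads$fe_t$enc), 0)
  expect_gt(norm_of(grads$fe_t$ln), 0)
  expect_gt(norm_of(grads$fc1), 0)
  expect_gt(norm_of(grads$fc2), 0)
  expect_gt(norm_of(grads$fe_e$bn1), 0)
  expect_gt(norm_of(grads$fe_t$bn1), 0)
})

test_that("checkpoints reload bit-exactly", {
  net <- build_network(model_config(), seed = 10)
  x <- array(rnorm(4 * 2 * 64), c(4, 2, 64))
  p1 <- forward(net, x)
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(net, path)
  re <- load_checkpoint(path)
  expect_identical(re$params, net$params)
  expect_identical(forward(re, x), p1)
  bad <- withr::local_tempfile(fileext = ".rds")
  saveRDS(list(1, 2), bad)
  expect_error(load_checkpoint(bad), "not an errp_network")
})
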