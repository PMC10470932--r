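tiny_cfg <- function(...) {
  dcae_config(K = 3, kernel_size = 3, pool_size = 2, n_layers = 2,
              channels = c(2, 3), hidden_dim = 3, learning_rate = 0.05,
              epochs = 5, pretrain_epochs = 2, batch_size = 4, seed = 5, ...)
}

init_model <- function(cfg, len) {
  withr::with_seed(cfg$seed, circnea:::dcae_init(len, cfg))
}

test_that("attention weights live on the K-simplex and match a softmax oracle", {
  cfg <- tiny_cfg()
  layer <- init_model(cfg, 9)$layers[[1]]
  set.seed(30)
  x <- matrix(rnorm(1000 * 9), 1000, 9)
  pi <- attention_weights(layer, x)
  expect_equal(dim(pi), c(1000, 3))
  expect_true(all(pi >= 0 & pi <= 1))
  expect_lt(max(abs(rowSums(pi) - 1)), 1e-6)

  # independent recomputation: summary -> tanh bottleneck -> affine -> softmax
  s <- rowMeans(x)
  h <- tanh(outer(s, layer$W1) + matrix(layer$c1, 1000, 4, byrow = TRUE))
  logits <- h %*% layer$W2 + matrix(layer$c2, 1000, 3, byrow = TRUE)
  ex <- exp(logits)
  expect_lt(max(abs(pi - ex / rowSums(ex))), 1e-10)
})

test_that("K = 1 attention is identically one", {
  cfg <- dcae_config(K = 1, channels = c(1, 1), hidden_dim = 2, seed = 1)
  layer <- init_model(cfg, 8)$layers[[1]]
  set.seed(31)
  pi <- attention_weights(layer, matrix(rnorm(50 * 8), 50, 8))
  expect_identical(unname(pi), matrix(1, 50, 1))
})

test_that("dynamic convolution is the attention mixture of per-kernel convolutions", {
  cfg <- tiny_cfg()
  layer <- init_model(cfg, 9)$layers[[1]]
  set.seed(32)
  x <- matrix(rnorm(6 * 9), 6, 9)
  out <- dynamic_conv(layer, x)
  # oracle: convolve with each kernel bank separately, then mix with pi
  conv1 <- function(v, kern, bias) {
    vp <- c(0, v, 0)
    sapply(seq_along(v), function(j) sum(vp[j:(j + 2)] * kern) + bias)
  }
  for (b in 1:6) for (co in 1:2) {
    mix <- 0
    for (k in 1:3) {
      kern <- layer$Wk[k, (co - 1) * 3 + 1:3]
      mix <- mix + out$pi[b, k] * conv1(x[b, ], kern, layer$bk[k, co])
    }
    expect_equal(unname(out$t[b, , co]), unname(1 / (1 + exp(-mix))),
                 tolerance = 1e-6)
  }
})

test_that("analytic gradients match finite differences", {
  cfg <- tiny_cfg()
  set.seed(33)
  X <- matrix(runif(4 * 9), 4, 9)
  model <- init_model(cfg, 9)
  fwd <- circnea:::dcae_forward(model, X)
  gr <- circnea:::dcae_backward(model, X, fwd)
  eps <- 1e-5
  num <- function(set_get) {
    v <- set_get$get(model)
    vapply(seq_along(v), function(i) {
      m1 <- set_get$set(model, replace(v, i, v[i] + eps))
      m2 <- set_get$set(model, replace(v, i, v[i] - eps))
      (circnea:::dcae_forward(m1, X)$loss -
         circnea:::dcae_forward(m2, X)$loss) / (2 * eps) * ncol(X)
    }, numeric(1))
  }
  checks <- list(
    list(analytic = gr$layers[[1]]$gWk,
         get = function(m) m$layers[[1]]$Wk,
         set = function(m, v) { m$layers[[1]]$Wk[] <- v; m }),
    list(analytic = gr$layers[[2]]$gbkdec,
         get = function(m) m$layers[[2]]$bkdec,
         set = function(m, v) { m$layers[[2]]$bkdec[] <- v; m }),
    list(analytic = gr$layers[[1]]$gW2,
         get = function(m) m$layers[[1]]$W2,
         set = function(m, v) { m$layers[[1]]$W2[] <- v; m }),
    list(analytic = gr$Wh,
         get = function(m) m$Wh, set = function(m, v) { m$Wh[] <- v; m }),
    list(analytic = gr$bd,
         get = function(m) m$bd, set = function(m, v) { m$bd <- v; m }))
  for (ck in checks) {
    expect_lt(max(abs(as.vector(ck$analytic) - num(ck))), 1e-8)
  }
})

test_that("encoder and decoder shapes follow the pooling arithmetic", {
  set.seed(34)
  for (len in c(8, 13, 21)) {
    cfg <- tiny_cfg()
    feats <- matrix(runif(10 * len), 10, len)
    model <- dcae_train(feats, cfg)
    expect_equal(model$lengths, c(len, ceiling(len / 2), ceiling(len / 4)))
    y <- dcae_encode(model, feats)
    expect_equal(dim(y), c(10, 3))
    xhat <- dcae_decode(model, feats)
    expect_equal(dim(xhat), dim(feats))
    expect_true(all(xhat > 0 & xhat < 1))
    expect_true(all(is.finite(y)))
  }
})

test_that("training reduces reconstruction loss deterministically", {
  set.seed(35)
  blk <- rep(1:2, each = 10)
  feats <- outer(blk, rep(1, 12)) * 0.4 + matrix(runif(20 * 12), 20, 12) * 0.3
  cfg <- dcae_config(K = 2, channels = c(2, 4), hidden_dim = 6,
                     learning_rate = 0.3, epochs = 60, pretrain_epochs = 20,
                     batch_size = 10, seed = 7)
  m1 <- dcae_train(feats, cfg)
  expect_lt(m1$final_loss, m1$initial_loss)
  expect_length(m1$loss_trace, 60)
  expect_true(all(is.finite(m1$loss_trace)))
  m2 <- dcae_train(feats, cfg)
  expect_identical(m1$loss_trace, m2$loss_trace)
  expect_identical(m1$layers[[1]]$Wk, m2$layers[[1]]$Wk)
})

test_that("a repeated vector is memorized to near-zero error", {
  # one vector repeated: after min-max scaling the target is constant, and
  # the decoder must drive its sigmoid to reproduce it exactly
  set.seed(36)
  feats <- matrix(rep(runif(12), each = 8), 8, 12)
  cfg <- dcae_config(K = 2, channels = c(2, 4), hidden_dim = 6,
                     learning_rate = 1, epochs = 400, pretrain_epochs = 0,
                     batch_size = 8, seed = 8)
  m <- dcae_train(feats, cfg)
  expect_lt(m$final_loss, 1e-3)
})

test_that("K = 1 dynamic model is bit-identical to the static CAE", {
  set.seed(37)
  feats <- matrix(runif(30 * 14), 30, 14)
  cfg <- dcae_config(K = 1, channels = c(2, 3), hidden_dim = 5,
                     learning_rate = 0.2, epochs = 8, pretrain_epochs = 4,
                     batch_size = 10, seed = 9)
  dyn <- dcae_train(feats, cfg, static = FALSE)
  cae <- dcae_train(feats, cfg, static = TRUE)
  expect_identical(dyn$loss_trace, cae$loss_trace)
  expect_identical(dyn$pretrain_traces, cae$pretrain_traces)
  expect_identical(dyn$layers[[1]]$Wk, cae$layers[[1]]$Wk)
  expect_identical(dyn$layers[[2]]$Wk, cae$layers[[2]]$Wk)
  expect_identical(dyn$Wh, cae$Wh)
  expect_identical(dcae_encode(dyn, feats), dcae_encode(cae, feats))
})

test_that("static mode requires a single kernel bank", {
  feats <- matrix(runif(10 * 8), 10, 8)
  cfg <- dcae_config(K = 2, channels = c(1, 1), hidden_dim = 2,
                     epochs = 1, pretrain_epochs = 0, batch_size = 5)
  expect_error(dcae_train(feats, cfg, static = TRUE), "K = 1")
})
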