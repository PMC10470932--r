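# Dynamic convolutional autoencoder (DCAE).
#
# The encoder stacks dynamic 1-D convolution layers: K parallel kernel
# banks w_k (each C_out x C_in x ks) are mixed per sample by attention
# weights pi_k(x) on the K-simplex (global-average summary of x -> tanh
# bottleneck -> affine -> softmax),
#   W~(x) = sum_k pi_k(x) w_k,   b~(x) = sum_k pi_k(x) b_k,
#   t = sigmoid(W~(x) * x + b~(x)),  then per-channel max-pooling.
# The pooled top representation is flattened and mapped by affine+sigmoid
# to the hidden code y. The decoder mirrors this: affine+sigmoid back to
# the pooled shape, then per layer upsample + convolution with the
# *transposed* aggregated kernel (tied weights; its own attention-
# aggregated bias, since encoder and decoder channel counts differ) +
# sigmoid, down to the single-channel reconstruction x'.
# Training is plain gradient descent on the per-sample squared
# reconstruction error with analytic gradients: layerwise pretraining
# (each layer as a one-layer autoencoder), then joint fine-tuning.
# With K = 1 the softmax is identically 1 and the model collapses exactly
# to an ordinary convolutional autoencoder (the CAE baseline).

#' DCAE configuration
#'
#' @param K number of parallel kernel banks per dynamic layer.
#' @param kernel_size odd convolution kernel width.
#' @param pool_size max-pooling width.
#' @param n_layers number of dynamic convolution + pooling layers.
#' @param channels integer vector of output channels per layer (default
#'   4, 8, 16, ... doubling per layer).
#' @param hidden_dim dimension of the hidden code.
#' @param learning_rate gradient-descent step size.
#' @param epochs joint fine-tuning epochs.
#' @param pretrain_epochs per-layer pretraining epochs.
#' @param batch_size minibatch size.
#' @param seed seed covering initialization and batch shuffling.
#' @return a `dcae_config` list.
#' @export
dcae_config <- function(K = 4, kernel_size = 3, pool_size = 2, n_layers = 2,
                        channels = NULL, hidden_dim = 64,
                        learning_rate = 0.001, epochs = 300,
                        pretrain_epochs = 100, batch_size = 32, seed = 1) {
  assert_that(K >= 1, "K must be >= 1")
  assert_that(kernel_size %% 2 == 1, "kernel_size must be odd")
  assert_that(pool_size >= 1 && n_layers >= 1 && hidden_dim >= 1,
              "pool_size, n_layers, hidden_dim must be positive")
  assert_that(learning_rate > 0, "learning_rate must be positive")
  if (is.null(channels)) channels <- 4L * 2L^(seq_len(n_layers) - 1L)
  assert_that(length(channels) == n_layers && all(channels >= 1),
              "channels must give one positive count per layer")
  structure(list(K = as.integer(K), kernel_size = as.integer(kernel_size),
                 pool_size = as.integer(pool_size),
                 n_layers = as.integer(n_layers),
                 channels = as.integer(channels),
                 hidden_dim = as.integer(hidden_dim),
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 pretrain_epochs = as.integer(pretrain_epochs),
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed)),
            class = "dcae_config")
}

sigmoid <- function(x) 1 / (1 + exp(-x))

softmax_rows <- function(x) {
  e <- exp(x - apply(x, 1, max))
  e / rowSums(e)
}

# column block of the flattened kernel bank for (channel out, channel in):
# banks are stored K x (C_out*C_in*ks), components ordered (co, ci, u)
wslice <- function(co, ci, ks, cin) ((co - 1L) * cin + (ci - 1L)) * ks

# ---- initialization ---------------------------------------------------------

# Parameter draw order is fixed (kernel banks, then attention, per layer;
# then the affine maps) so a static (ordinary CAE) model and a dynamic
# model share identical initial weights under the same seed.
dcae_init_layer <- function(K, ks, cin, cout) {
  A <- max(K, 4L)
  sdk <- sqrt(1 / (cin * ks))
  list(cin = cin, cout = cout, ks = ks,
       Wk = matrix(stats::rnorm(K * cout * cin * ks, 0, sdk), K),
       bk = matrix(0, K, cout),
       bkdec = matrix(0, K, cin),
       W1 = stats::rnorm(A, 0, 0.1),
       c1 = numeric(A),
       W2 = matrix(stats::rnorm(A * K, 0, 0.1), A, K),
       c2 = numeric(K))
}

dcae_init <- function(input_len, cfg, static = FALSE) {
  lengths <- input_len
  for (l in seq_len(cfg$n_layers)) {
    lengths <- c(lengths, ceiling(lengths[l] / cfg$pool_size))
  }
  assert_that(lengths[cfg$n_layers + 1] >= 1,
              "input too short for the pooling stack")
  if (static) assert_that(cfg$K == 1L, "static (ordinary CAE) mode requires K = 1")
  cins <- c(1L, cfg$channels[-cfg$n_layers])
  layers <- lapply(seq_len(cfg$n_layers), function(l) {
    dcae_init_layer(cfg$K, cfg$kernel_size, cins[l], cfg$channels[l])
  })
  flat <- lengths[cfg$n_layers + 1] * cfg$channels[cfg$n_layers]
  H <- cfg$hidden_dim
  list(cfg = cfg, layers = layers, lengths = lengths, static = static,
       use_hidden = TRUE, flat = flat,
       Wh = matrix(stats::rnorm(flat * H, 0, 1 / sqrt(flat)), flat, H),
       bh = numeric(H),
       Wd = matrix(stats::rnorm(H * flat, 0, 1 / sqrt(H)), H, flat),
       bd = numeric(flat))
}

# ---- array helpers (signals are B x L x C arrays) ---------------------------

pad_signal <- function(X, pad) {
  d <- dim(X)
  if (pad == 0) return(X)
  out <- array(0, c(d[1], d[2] + 2 * pad, d[3]))
  out[, (pad + 1):(pad + d[2]), ] <- X
  out
}

maxpool_fwd <- function(T, pool) {
  d <- dim(T)
  Lp <- ceiling(d[2] / pool)
  P <- array(0, c(d[1], Lp, d[3]))
  idx <- array(0L, c(d[1], Lp, d[3]))
  rows <- seq_len(d[1])
  for (c in seq_len(d[3])) {
    for (g in seq_len(Lp)) {
      cols <- (((g - 1L) * pool + 1L):min(g * pool, d[2]))
      block <- T[, cols, c, drop = FALSE]
      dim(block) <- c(d[1], length(cols))
      j <- max.col(block, ties.method = "first")
      P[, g, c] <- block[cbind(rows, j)]
      idx[, g, c] <- cols[j]
    }
  }
  list(P = P, idx = idx)
}

maxpool_bwd <- function(dP, idx, L) {
  d <- dim(dP)
  dT <- array(0, c(d[1], L, d[3]))
  rows <- seq_len(d[1])
  for (c in seq_len(d[3])) {
    for (g in seq_len(d[2])) {
      cells <- cbind(rows, idx[, g, c], c)
      dT[cells] <- dT[cells] + dP[, g, c]
    }
  }
  dT
}

upsample_fwd <- function(D, pool, L_out) {
  d <- dim(D)
  U <- D[, rep(seq_len(d[2]), each = pool), , drop = FALSE]
  U[, seq_len(L_out), , drop = FALSE]
}

upsample_bwd <- function(dU, pool, Lp) {
  d <- dim(dU)
  dD <- array(0, c(d[1], Lp, d[3]))
  for (g in seq_len(Lp)) {
    cols <- (((g - 1L) * pool + 1L):min(g * pool, d[2]))
    if (cols[1] > d[2]) break
    block <- dU[, cols, , drop = FALSE]
    dD[, g, ] <- apply(block, c(1, 3), sum)
  }
  dD
}

# ---- attention --------------------------------------------------------------

attention_fwd <- function(layer, Xin, static) {
  B <- dim(Xin)[1]
  if (static) {
    return(list(pi = matrix(1, B, 1), s = NULL, h = NULL))
  }
  s <- rowMeans(matrix(Xin, B))
  h <- tanh(outer(s, layer$W1) +
              matrix(layer$c1, B, length(layer$c1), byrow = TRUE))
  logits <- h %*% layer$W2 + matrix(layer$c2, B, length(layer$c2), byrow = TRUE)
  list(pi = softmax_rows(logits), s = s, h = h)
}

attention_bwd <- function(layer, cache, dWagg, dbagg, dbaggdec, static) {
  B <- nrow(dWagg)
  gWk <- crossprod(cache$pi, dWagg)
  gbk <- crossprod(cache$pi, dbagg)
  gbkdec <- crossprod(cache$pi, dbaggdec)
  base <- list(gWk = gWk, gbk = gbk, gbkdec = gbkdec,
               gW1 = numeric(length(layer$W1)),
               gc1 = numeric(length(layer$c1)),
               gW2 = matrix(0, nrow(layer$W2), ncol(layer$W2)),
               gc2 = numeric(length(layer$c2)))
  din <- dim(cache$Xin)
  if (static) {
    base$dX_att <- array(0, din)
    return(base)
  }
  dpi <- dWagg %*% t(layer$Wk) + dbagg %*% t(layer$bk) +
    dbaggdec %*% t(layer$bkdec)
  dlogits <- cache$pi * (dpi - rowSums(dpi * cache$pi))
  base$gW2 <- crossprod(cache$h, dlogits)
  base$gc2 <- colSums(dlogits)
  dh <- dlogits %*% t(layer$W2)
  dpre <- dh * (1 - cache$h^2)
  base$gW1 <- colSums(dpre * cache$s)
  base$gc1 <- colSums(dpre)
  ds <- as.vector(dpre %*% layer$W1)
  base$dX_att <- array(ds / (din[2] * din[3]), din)
  base
}

# ---- layer forward / decoder inverse ----------------------------------------

layer_fwd <- function(layer, Xin, pool, pad, static) {
  att <- attention_fwd(layer, Xin, static)
  Wagg <- att$pi %*% layer$Wk
  bagg <- att$pi %*% layer$bk
  baggdec <- att$pi %*% layer$bkdec
  B <- dim(Xin)[1]; L <- dim(Xin)[2]
  ks <- layer$ks; cin <- layer$cin; cout <- layer$cout
  Xp <- pad_signal(Xin, pad)
  Zpre <- array(0, c(B, L, cout))
  for (co in seq_len(cout)) {
    acc <- matrix(bagg[, co], B, L)
    for (ci in seq_len(cin)) {
      base <- wslice(co, ci, ks, cin)
      for (u in seq_len(ks)) {
        acc <- acc + Xp[, u:(u + L - 1), ci] * Wagg[, base + u]
      }
    }
    Zpre[, , co] <- acc
  }
  T <- sigmoid(Zpre)
  mp <- maxpool_fwd(T, pool)
  list(Xin = Xin, Xp = Xp, pi = att$pi, s = att$s, h = att$h,
       Wagg = Wagg, bagg = bagg, baggdec = baggdec,
       T = T, P = mp$P, idx = mp$idx)
}

# transposed convolution: from C_out channels back to C_in channels with
# the reversed tied kernel plus the layer's decoder bias
dec_fwd <- function(layer, cache, D, pool, pad, L_out) {
  U <- upsample_fwd(D, pool, L_out)
  Up <- pad_signal(U, pad)
  B <- dim(U)[1]
  ks <- layer$ks; cin <- layer$cin; cout <- layer$cout
  Rpre <- array(0, c(B, L_out, cin))
  for (ci in seq_len(cin)) {
    acc <- matrix(cache$baggdec[, ci], B, L_out)
    for (co in seq_len(cout)) {
      base <- wslice(co, ci, ks, cin)
      for (u in seq_len(ks)) {
        acc <- acc + Up[, u:(u + L_out - 1), co] * cache$Wagg[, base + ks + 1L - u]
      }
    }
    Rpre[, , ci] <- acc
  }
  list(U = U, Up = Up, R = sigmoid(Rpre))
}

# ---- full forward / backward ------------------------------------------------

dcae_forward <- function(model, X) {
  cfg <- model$cfg
  pad <- (cfg$kernel_size - 1L) %/% 2L
  n <- length(model$layers)
  B <- nrow(X)
  caches <- vector("list", n)
  cur <- array(X, c(B, ncol(X), 1L))
  for (l in seq_len(n)) {
    caches[[l]] <- layer_fwd(model$layers[[l]], cur, cfg$pool_size, pad,
                             model$static)
    cur <- caches[[l]]$P
  }
  P_top <- cur
  top_dim <- dim(P_top)
  Pflat <- matrix(P_top, B)
  if (model$use_hidden) {
    Y <- sigmoid(Pflat %*% model$Wh +
                   matrix(model$bh, B, length(model$bh), byrow = TRUE))
    D0flat <- sigmoid(Y %*% model$Wd +
                        matrix(model$bd, B, length(model$bd), byrow = TRUE))
  } else {
    Y <- Pflat
    D0flat <- Pflat
  }
  dec <- vector("list", n)
  D <- array(D0flat, top_dim)
  for (l in rev(seq_len(n))) {
    dec[[l]] <- dec_fwd(model$layers[[l]], caches[[l]], D, cfg$pool_size, pad,
                        model$lengths[l])
    D <- dec[[l]]$R
  }
  Xhat <- matrix(D, B)
  list(caches = caches, dec = dec, Pflat = Pflat, top_dim = top_dim, Y = Y,
       D0flat = D0flat, Xhat = Xhat, loss = mean((X - Xhat)^2))
}

dcae_backward <- function(model, X, fwd) {
  cfg <- model$cfg
  pad <- (cfg$kernel_size - 1L) %/% 2L
  ks <- cfg$kernel_size
  n <- length(model$layers)
  B <- nrow(X)
  grads <- list(layers = vector("list", n))
  dWagg_dec <- vector("list", n)
  dbaggdec_dec <- vector("list", n)

  # objective: mean over samples of ||x - x'||^2 (per-element MSE times the
  # signal length; traces report the per-element MSE)
  dR <- array(2 * (fwd$Xhat - X) / B, c(B, ncol(X), 1L))

  # decoder was applied layers n..1, so backprop runs 1..n
  for (l in seq_len(n)) {
    layer <- model$layers[[l]]
    cin <- layer$cin; cout <- layer$cout
    R <- fwd$dec[[l]]$R
    Up <- fwd$dec[[l]]$Up
    L_out <- dim(R)[2]
    dRpre <- dR * R * (1 - R)
    dWagg <- matrix(0, B, ncol(layer$Wk))
    dUp <- array(0, dim(Up))
    dbdec <- matrix(0, B, cin)
    for (ci in seq_len(cin)) {
      dRc <- dRpre[, , ci]
      if (is.null(dim(dRc))) dRc <- matrix(dRc, B)
      dbdec[, ci] <- rowSums(dRc)
      for (co in seq_len(cout)) {
        base <- wslice(co, ci, ks, cin)
        for (u in seq_len(ks)) {
          cols <- u:(u + L_out - 1)
          widx <- base + ks + 1L - u
          dWagg[, widx] <- dWagg[, widx] + rowSums(dRc * Up[, cols, co])
          dUp[, cols, co] <- dUp[, cols, co] + dRc * fwd$caches[[l]]$Wagg[, widx]
        }
      }
    }
    dWagg_dec[[l]] <- dWagg
    dbaggdec_dec[[l]] <- dbdec
    dU <- dUp[, (pad + 1):(pad + L_out), , drop = FALSE]
    dR <- upsample_bwd(dU, cfg$pool_size, model$lengths[l + 1])
  }
  dD0 <- matrix(dR, B)

  if (model$use_hidden) {
    D0 <- fwd$D0flat; Y <- fwd$Y
    dD0pre <- dD0 * D0 * (1 - D0)
    grads$Wd <- crossprod(Y, dD0pre)
    grads$bd <- colSums(dD0pre)
    dY <- dD0pre %*% t(model$Wd)
    dYpre <- dY * Y * (1 - Y)
    grads$Wh <- crossprod(fwd$Pflat, dYpre)
    grads$bh <- colSums(dYpre)
    dPflat <- dYpre %*% t(model$Wh)
  } else {
    dPflat <- dD0
  }
  dP <- array(dPflat, fwd$top_dim)

  # encoder
  for (l in rev(seq_len(n))) {
    layer <- model$layers[[l]]
    cache <- fwd$caches[[l]]
    cin <- layer$cin; cout <- layer$cout
    L <- dim(cache$T)[2]
    dT <- maxpool_bwd(dP, cache$idx, L)
    dZpre <- dT * cache$T * (1 - cache$T)
    dWagg <- dWagg_dec[[l]]
    dbagg <- matrix(0, B, cout)
    dXp <- array(0, dim(cache$Xp))
    for (co in seq_len(cout)) {
      dZc <- dZpre[, , co]
      if (is.null(dim(dZc))) dZc <- matrix(dZc, B)
      dbagg[, co] <- rowSums(dZc)
      for (ci in seq_len(cin)) {
        base <- wslice(co, ci, ks, cin)
        for (u in seq_len(ks)) {
          cols <- u:(u + L - 1)
          dWagg[, base + u] <- dWagg[, base + u] +
            rowSums(dZc * cache$Xp[, cols, ci])
          dXp[, cols, ci] <- dXp[, cols, ci] + dZc * cache$Wagg[, base + u]
        }
      }
    }
    ab <- attention_bwd(layer, cache, dWagg, dbagg, dbaggdec_dec[[l]],
                        model$static)
    grads$layers[[l]] <- ab[c("gWk", "gbk", "gbkdec", "gW1", "gc1", "gW2",
                              "gc2")]
    dP <- dXp[, (pad + 1):(pad + L), , drop = FALSE] + ab$dX_att
  }
  grads
}

dcae_update <- function(model, grads, lr) {
  for (l in seq_along(model$layers)) {
    g <- grads$layers[[l]]
    ly <- model$layers[[l]]
    ly$Wk <- ly$Wk - lr * g$gWk
    ly$bk <- ly$bk - lr * g$gbk
    ly$bkdec <- ly$bkdec - lr * g$gbkdec
    ly$W1 <- ly$W1 - lr * g$gW1
    ly$c1 <- ly$c1 - lr * g$gc1
    ly$W2 <- ly$W2 - lr * g$gW2
    ly$c2 <- ly$c2 - lr * g$gc2
    model$layers[[l]] <- ly
  }
  if (model$use_hidden && !is.null(grads$Wh)) {
    model$Wh <- model$Wh - lr * grads$Wh
    model$bh <- model$bh - lr * grads$bh
    model$Wd <- model$Wd - lr * grads$Wd
    model$bd <- model$bd - lr * grads$bd
  }
  model
}

train_loop <- function(model, X, epochs, lr, batch_size) {
  B <- nrow(X)
  trace <- numeric(epochs)
  if (epochs == 0) return(list(model = model, trace = trace))
  for (ep in seq_len(epochs)) {
    perm <- sample.int(B)
    starts <- seq(1, B, by = batch_size)
    tot <- 0
    for (s0 in starts) {
      rows <- perm[s0:min(s0 + batch_size - 1L, B)]
      Xb <- X[rows, , drop = FALSE]
      fwd <- dcae_forward(model, Xb)
      if (!is.finite(fwd$loss)) stop("NaN loss; lr too high", call. = FALSE)
      grads <- dcae_backward(model, Xb, fwd)
      model <- dcae_update(model, grads, lr)
      tot <- tot + fwd$loss * length(rows)
    }
    trace[ep] <- tot / B
  }
  list(model = model, trace = trace)
}

# ---- public surface ---------------------------------------------------------

#' Attention weights of a dynamic convolution layer
#'
#' Maps each input sample to a point on the K-simplex: global-average
#' summary, tanh bottleneck, affine map, softmax over the K kernel banks.
#' With K = 1 the output is identically 1.
#'
#' @param layer one element of a model's `layers` list.
#' @param x input, one sample per row (matrix or single vector); any channel
#'   layout flattened per sample.
#' @return matrix of attention weights (samples x K), rows summing to 1.
#' @export
attention_weights <- function(layer, x) {
  if (is.null(dim(x))) x <- matrix(x, 1)
  if (length(dim(x)) == 2) x <- array(x, c(nrow(x), ncol(x), 1L))
  attention_fwd(layer, x, static = FALSE)$pi
}

#' Dynamic convolution of a 1-D signal
#'
#' Aggregates the layer's K kernel banks with the input's attention
#' weights, convolves ("same" padding), adds the aggregated bias and
#' applies the sigmoid.
#'
#' @inheritParams attention_weights
#' @return list with `t` (activations, samples x length x channels_out),
#'   `pi`, `Wagg`, `bagg`.
#' @export
dynamic_conv <- function(layer, x) {
  if (is.null(dim(x))) x <- matrix(x, 1)
  if (length(dim(x)) == 2) x <- array(x, c(nrow(x), ncol(x), 1L))
  cache <- layer_fwd(layer, x, pool = 1L, pad = (layer$ks - 1L) %/% 2L,
                     static = FALSE)
  list(t = cache$T, pi = cache$pi, Wagg = cache$Wagg, bagg = cache$bagg)
}

scale_features <- function(X, scaler) {
  sweep(sweep(X, 2, scaler$min), 2, scaler$range, "/")
}

#' Train a dynamic convolutional autoencoder
#'
#' Features are min-max scaled to [0, 1] (scaler persisted in the model).
#' Training is layerwise: each dynamic layer is first trained as a
#' one-layer autoencoder on its input representation (`pretrain_epochs`
#' each), then the full encoder/decoder (including the hidden affine maps)
#' is fine-tuned jointly for `epochs` epochs. All randomness (init, batch
#' shuffling) is governed by `cfg$seed`.
#'
#' @param features numeric matrix of feature vectors, one sample per row.
#' @param cfg a [dcae_config()].
#' @param static train an ordinary convolutional autoencoder instead
#'   (requires `K = 1`): identical code path with the attention fixed at 1.
#' @return object of class `dcae_model` with the trained parameters,
#'   `scaler`, `initial_loss` (untrained full-model reconstruction MSE),
#'   `loss_trace` (joint phase, per-element MSE), `pretrain_traces` and
#'   `final_loss`.
#' @export
dcae_train <- function(features, cfg = dcae_config(), static = FALSE) {
  assert_that(is.matrix(features) && nrow(features) >= 2,
              "need a matrix of >= 2 feature vectors")
  assert_that(!anyNA(features), "features contain NA")
  scaler <- list(min = apply(features, 2, min),
                 range = pmax(apply(features, 2, max) - apply(features, 2, min),
                              .Machine$double.eps))
  X <- scale_features(features, scaler)
  lr <- cfg$learning_rate
  res <- NULL; final <- NULL

  withr::with_seed(cfg$seed, {
    model <- dcae_init(ncol(X), cfg, static = static)
    initial_loss <- dcae_forward(model, X)$loss

    pretrain_traces <- vector("list", cfg$n_layers)
    cur <- X
    pad <- (cfg$kernel_size - 1L) %/% 2L
    for (l in seq_len(cfg$n_layers)) {
      sub <- list(cfg = cfg, layers = model$layers[l],
                  lengths = model$lengths[l:(l + 1)], static = model$static,
                  use_hidden = FALSE)
      res_l <- train_loop_multi(sub, cur, cfg$pretrain_epochs, lr,
                                cfg$batch_size)
      model$layers[[l]] <- res_l$model$layers[[1]]
      pretrain_traces[[l]] <- res_l$trace
      cur <- advance_representation(model$layers[[l]], cur, cfg, pad,
                                    model$static)
    }

    res <- train_loop(model, X, cfg$epochs, lr, cfg$batch_size)
    model <- res$model
    final <- dcae_forward(model, X)
  })

  model$scaler <- scaler
  model$initial_loss <- initial_loss
  model$pretrain_traces <- pretrain_traces
  model$loss_trace <- res$trace
  model$final_loss <- final$loss
  class(model) <- "dcae_model"
  model
}

# pretraining operates on multi-channel representations flattened to a
# matrix (B x L*C); these helpers rebuild the array views
train_loop_multi <- function(model, Xflat, epochs, lr, batch_size) {
  cin <- model$layers[[1]]$cin
  L <- model$lengths[1]
  B <- nrow(Xflat)
  trace <- numeric(epochs)
  if (epochs == 0) return(list(model = model, trace = trace))
  pad <- (model$cfg$kernel_size - 1L) %/% 2L
  for (ep in seq_len(epochs)) {
    perm <- sample.int(B)
    starts <- seq(1, B, by = batch_size)
    tot <- 0
    for (s0 in starts) {
      rows <- perm[s0:min(s0 + batch_size - 1L, B)]
      Xb <- array(Xflat[rows, , drop = FALSE], c(length(rows), L, cin))
      fb <- pretrain_step(model, Xb, pad)
      if (!is.finite(fb$loss)) stop("NaN loss; lr too high", call. = FALSE)
      model$layers[[1]] <- pretrain_update(model$layers[[1]], fb$grads, lr)
      tot <- tot + fb$loss * length(rows)
    }
    trace[ep] <- tot / B
  }
  list(model = model, trace = trace)
}

pretrain_step <- function(model, Xb, pad) {
  cfg <- model$cfg
  layer <- model$layers[[1]]
  B <- dim(Xb)[1]
  cache <- layer_fwd(layer, Xb, cfg$pool_size, pad, model$static)
  dec <- dec_fwd(layer, cache, cache$P, cfg$pool_size, pad, model$lengths[1])
  loss <- mean((Xb - dec$R)^2)
  ks <- layer$ks; cin <- layer$cin; cout <- layer$cout
  L_out <- dim(dec$R)[2]
  dR <- 2 * (dec$R - Xb) / B
  dRpre <- dR * dec$R * (1 - dec$R)
  dWagg <- matrix(0, B, ncol(layer$Wk))
  dUp <- array(0, dim(dec$Up))
  dbdec <- matrix(0, B, cin)
  for (ci in seq_len(cin)) {
    dRc <- matrix(dRpre[, , ci], B)
    dbdec[, ci] <- rowSums(dRc)
    for (co in seq_len(cout)) {
      base <- wslice(co, ci, ks, cin)
      for (u in seq_len(ks)) {
        cols <- u:(u + L_out - 1)
        widx <- base + ks + 1L - u
        dWagg[, widx] <- dWagg[, widx] + rowSums(dRc * dec$Up[, cols, co])
        dUp[, cols, co] <- dUp[, cols, co] + dRc * cache$Wagg[, widx]
      }
    }
  }
  dU <- dUp[, (pad + 1):(pad + L_out), , drop = FALSE]
  dP <- upsample_bwd(dU, cfg$pool_size, dim(cache$P)[2])
  L <- dim(cache$T)[2]
  dT <- maxpool_bwd(dP, cache$idx, L)
  dZpre <- dT * cache$T * (1 - cache$T)
  dbagg <- matrix(0, B, cout)
  for (co in seq_len(cout)) {
    dZc <- matrix(dZpre[, , co], B)
    dbagg[, co] <- rowSums(dZc)
    for (ci in seq_len(cin)) {
      base <- wslice(co, ci, ks, cin)
      for (u in seq_len(ks)) {
        cols <- u:(u + L - 1)
        dWagg[, base + u] <- dWagg[, base + u] +
          rowSums(dZc * cache$Xp[, cols, ci])
      }
    }
  }
  ab <- attention_bwd(layer, cache, dWagg, dbagg, dbdec, model$static)
  list(loss = loss,
       grads = ab[c("gWk", "gbk", "gbkdec", "gW1", "gc1", "gW2", "gc2")])
}

pretrain_update <- function(ly, g, lr) {
  ly$Wk <- ly$Wk - lr * g$gWk
  ly$bk <- ly$bk - lr * g$gbk
  ly$bkdec <- ly$bkdec - lr * g$gbkdec
  ly$W1 <- ly$W1 - lr * g$gW1
  ly$c1 <- ly$c1 - lr * g$gc1
  ly$W2 <- ly$W2 - lr * g$gW2
  ly$c2 <- ly$c2 - lr * g$gc2
  ly
}

advance_representation <- function(layer, Xflat, cfg, pad, static) {
  B <- nrow(Xflat)
  L <- ncol(Xflat) / layer$cin
  Xb <- array(Xflat, c(B, L, layer$cin))
  P <- layer_fwd(layer, Xb, cfg$pool_size, pad, static)$P
  matrix(P, B)
}

#' @export
print.dcae_model <- function(x, ...) {
  cat("dcae_model:", length(x$layers), "layer(s), K =", x$cfg$K,
      ", channels", paste(x$cfg$channels, collapse = "/"),
      ", hidden", x$cfg$hidden_dim, "; MSE",
      format(x$initial_loss, digits = 4), "->",
      format(x$final_loss, digits = 4), "\n")
  invisible(x)
}

#' Encode feature vectors to the hidden representation
#'
#' Applies the persisted min-max scaler and the encoder (dynamic
#' convolutions, pooling, hidden affine map). This hidden vector is what
#' downstream classification consumes.
#'
#' @param model a trained `dcae_model`.
#' @param features numeric matrix, one sample per row (original scale).
#' @return matrix of hidden codes (samples x hidden_dim).
#' @export
dcae_encode <- function(model, features) {
  stopifnot(inherits(model, "dcae_model"))
  if (is.null(dim(features))) features <- matrix(features, 1)
  X <- scale_features(features, model$scaler)
  dcae_forward(model, X)$Y
}

#' Reconstruct feature vectors through the autoencoder
#'
#' Runs the full encoder/decoder. The decoder reuses the per-sample
#' aggregated kernels, so the original input is required for the attention
#' weights; reconstruction is a training-time diagnostic, not an inference
#' path.
#'
#' @inheritParams dcae_encode
#' @return matrix of reconstructions on the scaled [0, 1] feature scale.
#' @export
dcae_decode <- function(model, features) {
  stopifnot(inherits(model, "dcae_model"))
  if (is.null(dim(features))) features <- matrix(features, 1)
  X <- scale_features(features, model$scaler)
  dcae_forward(model, X)$Xhat
}
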