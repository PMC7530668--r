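# Minimal CNN engine backing the two classifier architectures.
# Convolutions run in compiled code (src/conv_ops.cpp); batch
# normalization, ReLU, dropout, dense layers, the Adam optimizer and the
# training loop live here. Everything is deterministic given the seed:
# one seed drives parameter initialization, batch shuffling and dropout.

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

new_conv_layer <- function(kind, k, cin, cout, stride = 2L, dropout = 0.1) {
  ksz <- prod(k)
  list(kind = kind, k = k, stride = as.integer(stride),
       pad = as.integer(floor(k[1] / 2)), cin = cin, cout = cout,
       dropout = dropout,
       w = matrix(0, ksz * cin, cout), b = numeric(cout),
       gamma = rep(1, cout), beta = numeric(cout),
       rmean = numeric(cout), rvar = rep(1, cout))
}

new_dense_layer <- function(nin, nout, act = "relu") {
  list(kind = "dense", nin = nin, nout = nout, act = act,
       w = matrix(0, nin, nout), b = numeric(nout))
}

init_layer <- function(layer) {
  if (layer$kind == "dense") {
    layer$w <- matrix(rnorm(length(layer$w), 0, sqrt(2 / layer$nin)),
                      nrow(layer$w), ncol(layer$w))
    layer$b <- numeric(layer$nout)
  } else {
    fan_in <- nrow(layer$w)
    layer$w <- matrix(rnorm(length(layer$w), 0, sqrt(2 / fan_in)),
                      nrow(layer$w), ncol(layer$w))
    layer$b <- numeric(layer$cout)
    layer$gamma <- rep(1, layer$cout); layer$beta <- numeric(layer$cout)
    layer$rmean <- numeric(layer$cout); layer$rvar <- rep(1, layer$cout)
  }
  layer
}

# per-channel broadcast helper: v has length n_channels = dim(z)[ch_dim],
# expanded to the shape of z (channel dim is 2 for 1-D maps, 3 for 2-D)
bcast <- function(v, z, ch_dim) {
  d <- dim(z)
  each <- prod(d[seq_len(ch_dim - 1L)])
  rep(v, each = each)                  # recycles over trailing dims
}

channel_sums <- function(z, ch_dim) {
  if (ch_dim == 2L) rowSums(colSums(z))              # (L, C, N)
  else rowSums(colSums(z, dims = 2L))                # (H, W, C, N)
}

conv_block_fw <- function(layer, x, training, ch_dim) {
  z <- if (layer$kind == "conv1d")
    conv1d_fw(x, layer$w, layer$b, layer$stride, layer$pad)
  else
    conv2d_fw(x, layer$w, layer$b, layer$stride, layer$pad,
              layer$k[1], layer$k[2])
  d <- dim(z); m <- prod(d) / d[ch_dim]
  if (training) {
    mu <- channel_sums(z, ch_dim) / m
    va <- channel_sums(z^2, ch_dim) / m - mu^2
    layer$rmean <- (1 - BN_MOMENTUM) * layer$rmean + BN_MOMENTUM * mu
    layer$rvar <- (1 - BN_MOMENTUM) * layer$rvar + BN_MOMENTUM * va
  } else { mu <- layer$rmean; va <- layer$rvar }
  inv_sd <- 1 / sqrt(va + BN_EPS)
  xhat <- (z - bcast(mu, z, ch_dim)) * bcast(inv_sd, z, ch_dim)
  y <- bcast(layer$gamma, z, ch_dim) * xhat + bcast(layer$beta, z, ch_dim)
  relu_mask <- y > 0
  y <- y * relu_mask
  drop_mask <- NULL
  if (training && layer$dropout > 0) {
    drop_mask <- (array(runif(length(y)), dim(y)) >= layer$dropout) /
      (1 - layer$dropout)
    y <- y * drop_mask
  }
  list(out = y, layer = layer,
       cache = list(x = x, z = z, xhat = xhat, mu = mu, inv_sd = inv_sd,
                    relu_mask = relu_mask, drop_mask = drop_mask, m = m))
}

conv_block_bw <- function(layer, cache, g, ch_dim) {
  if (!is.null(cache$drop_mask)) g <- g * cache$drop_mask
  g <- g * cache$relu_mask
  ggamma <- channel_sums(g * cache$xhat, ch_dim)
  gbeta <- channel_sums(g, ch_dim)
  gxhat <- g * bcast(layer$gamma, g, ch_dim)
  m <- cache$m
  s1 <- channel_sums(gxhat, ch_dim)
  s2 <- channel_sums(gxhat * cache$xhat, ch_dim)
  gz <- bcast(cache$inv_sd, g, ch_dim) *
    (gxhat - bcast(s1 / m, g, ch_dim) -
       cache$xhat * bcast(s2 / m, g, ch_dim))
  bw <- if (layer$kind == "conv1d")
    conv1d_bw(cache$x, layer$w, gz, layer$stride, layer$pad)
  else
    conv2d_bw(cache$x, layer$w, gz, layer$stride, layer$pad,
              layer$k[1], layer$k[2])
  list(gx = bw$gx,
       grads = list(w = bw$gw, b = bw$gb, gamma = ggamma, beta = gbeta))
}

dense_fw <- function(layer, x, training) {
  y <- x %*% layer$w + matrix(layer$b, nrow(x), layer$nout, byrow = TRUE)
  relu_mask <- NULL
  if (layer$act == "relu") { relu_mask <- y > 0; y <- y * relu_mask }
  list(out = y, cache = list(x = x, relu_mask = relu_mask))
}

dense_bw <- function(layer, cache, g) {
  if (!is.null(cache$relu_mask)) g <- g * cache$relu_mask
  list(gx = g %*% t(layer$w),
       grads = list(w = t(cache$x) %*% g, b = colSums(g)))
}

branch_fw <- function(layers, x, training, ch_dim) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    r <- conv_block_fw(layers[[i]], x, training, ch_dim)
    layers[[i]] <- r$layer
    caches[[i]] <- r$cache
    x <- r$out
  }
  list(out = x, layers = layers, caches = caches)
}

branch_bw <- function(layers, caches, g, ch_dim) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    r <- conv_block_bw(layers[[i]], caches[[i]], g, ch_dim)
    grads[[i]] <- r$grads
    g <- r$gx
  }
  grads
}

flatten_maps <- function(z) {
  d <- dim(z); n <- d[length(d)]
  t(matrix(z, prod(d[-length(d)]), n))
}

unflatten_maps <- function(g, d) array(t(g), d)

# stable binary cross-entropy on logits; gradient is (sigmoid(z) - y)/N
bce_with_logits <- function(z, y) {
  mean(pmax(z, 0) - z * y + log1p(exp(-abs(z))))
}

sigmoid <- function(z) 1 / (1 + exp(-z))

adam_step <- function(params, grads, state, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (is.null(state[[nm]])) state[[nm]] <- list(m = g * 0, v = g * 0)
    st <- state[[nm]]
    st$m <- beta1 * st$m + (1 - beta1) * g
    st$v <- beta2 * st$v + (1 - beta2) * g^2
    state[[nm]] <- st
    mhat <- st$m / (1 - beta1^t); vhat <- st$v / (1 - beta2^t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# flatten all trainable tensors of a model into one named list
collect_params <- function(model) {
  out <- list()
  grab <- function(layers, prefix) {
    for (i in seq_along(layers)) {
      ly <- layers[[i]]
      nms <- if (ly$kind == "dense") c("w", "b") else c("w", "b", "gamma", "beta")
      for (nm in nms) out[[paste0(prefix, i, ".", nm)]] <<- ly[[nm]]
    }
  }
  for (part in model$parts) grab(model[[part]], paste0(part, "."))
  out
}

restore_params <- function(model, params) {
  for (part in model$parts) {
    for (i in seq_along(model[[part]])) {
      ly <- model[[part]][[i]]
      nms <- if (ly$kind == "dense") c("w", "b") else c("w", "b", "gamma", "beta")
      for (nm in nms)
        model[[part]][[i]][[nm]] <- params[[paste0(part, ".", i, ".", nm)]]
    }
  }
  model
}

# batch-norm running statistics, captured alongside checkpoints
collect_bn_stats <- function(model) {
  out <- list()
  for (part in model$parts) {
    for (i in seq_along(model[[part]])) {
      ly <- model[[part]][[i]]
      if (ly$kind != "dense") {
        out[[paste0(part, ".", i, ".rmean")]] <- ly$rmean
        out[[paste0(part, ".", i, ".rvar")]] <- ly$rvar
      }
    }
  }
  out
}

restore_bn_stats <- function(model, stats) {
  for (part in model$parts) {
    for (i in seq_along(model[[part]])) {
      if (model[[part]][[i]]$kind != "dense") {
        model[[part]][[i]]$rmean <- stats[[paste0(part, ".", i, ".rmean")]]
        model[[part]][[i]]$rvar <- stats[[paste0(part, ".", i, ".rvar")]]
      }
    }
  }
  model
}
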