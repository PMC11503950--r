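# Dual-channel 3D U-Net, hand-rolled on the Rcpp kernels in src/kernels.cpp.
#
# Topology (depth = 3): three encoder blocks, each two [conv3 -> batch norm
# -> LeakyReLU] layers followed by 2x2x2 max-pooling (stride 2) and dropout
# 0.5; filters double per block (base, 2*base, 4*base; the full-scale
# profile is 16 -> 64). Three decoder blocks, each trilinear upsampling x2,
# concatenation with the matching encoder skip, then one [conv3 -> batch
# norm -> ReLU]. Final 3x3x3 convolution to one channel with a sigmoid, so
# outputs live in (0, 1).

#' Model configuration for the 3D U-Net
#'
#' @param grid_size cube edge of the model grid in voxels (divisible by
#'   `2^depth`; default 96, scalable down to 16 for desk-scale training).
#' @param base_filters filters of the first encoder block (doubling per
#'   block; default 16, i.e. 16 -> 64 over three blocks).
#' @param depth number of encoder blocks (default 3).
#' @param in_channels input channels (2: lesion mask + fixed average
#'   disconnectome template).
#' @param dropout dropout rate applied after each pooling (default 0.5).
#' @param leaky_slope negative slope of the encoder LeakyReLU (default 0.01).
#' @param voxel_size model-grid voxel size in mm.
#' @return A `model_config` object.
#' @export
model_config <- function(grid_size = 96, base_filters = 16, depth = 3,
                         in_channels = 2, dropout = 0.5, leaky_slope = 0.01,
                         voxel_size = 2) {
  if (base_filters < 1) stop("base_filters must be >= 1")
  if (grid_size %% (2^depth) != 0)
    stop(sprintf("model grid %d is not divisible by 2^%d", grid_size, depth))
  structure(list(grid_size = as.integer(grid_size),
                 base_filters = as.integer(base_filters),
                 depth = as.integer(depth),
                 in_channels = as.integer(in_channels),
                 dropout = dropout, leaky_slope = leaky_slope,
                 model_grid = grid_spec(rep(grid_size, 3), voxel_size)),
            class = "model_config")
}

#' Training configuration
#'
#' Defaults follow the reference recipe: batch size 4, Adam with learning
#' rate 3e-4 and weight decay 1e-4, up to 300 epochs with early stopping
#' after 50 epochs without validation improvement, 80/20 split.
#'
#' @param batch_size,learning_rate,weight_decay,max_epochs,early_stop_patience,split_fraction,seed
#'   scalars; see description.
#' @return A `train_config` object.
#' @export
train_config <- function(batch_size = 4, learning_rate = 3e-4,
                         weight_decay = 1e-4, max_epochs = 300,
                         early_stop_patience = 50, split_fraction = 0.8,
                         seed = 1) {
  if (split_fraction <= 0 || split_fraction >= 1)
    stop("split_fraction must be in (0, 1)")
  if (early_stop_patience > max_epochs)
    stop("patience must be <= max_epochs")
  structure(list(batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, weight_decay = weight_decay,
                 max_epochs = as.integer(max_epochs),
                 early_stop_patience = as.integer(early_stop_patience),
                 split_fraction = split_fraction, seed = as.integer(seed)),
            class = "train_config")
}

conv_init <- function(ci, co) {
  fan_in <- 27 * ci
  w <- array(stats::rnorm(27 * ci * co, sd = sqrt(2 / fan_in)),
             dim = c(3, 3, 3, ci, co))
  list(w = w, b = numeric(co))
}

bn_init <- function(c) {
  list(gamma = rep(1, c), beta = rep(0, c),
       run_mean = rep(0, c), run_var = rep(1, c))
}

#' Build an untrained 3D U-Net
#'
#' Weight initialization is He-normal for convolutions (seeded through R's
#' RNG) and unit-gain for batch-norm layers.
#'
#' @param cfg a [model_config()].
#' @param seed integer seed for weight initialization.
#' @return A `unet` object holding the configuration and all parameters.
#' @export
build_unet <- function(cfg = model_config(), seed = 1) {
  f <- as.integer(cfg$base_filters * 2^(0:(cfg$depth - 1)))
  with_seed(seed, {
    params <- list()
    ci <- cfg$in_channels
    for (i in seq_len(cfg$depth)) {
      params[[sprintf("enc%d_conv1", i)]] <- conv_init(ci, f[i])
      params[[sprintf("enc%d_bn1", i)]] <- bn_init(f[i])
      params[[sprintf("enc%d_conv2", i)]] <- conv_init(f[i], f[i])
      params[[sprintf("enc%d_bn2", i)]] <- bn_init(f[i])
      ci <- f[i]
    }
    # decoder: deepest first; input = upsampled previous + skip
    prev <- f[cfg$depth]
    for (i in rev(seq_len(cfg$depth))) {
      params[[sprintf("dec%d_conv", i)]] <- conv_init(prev + f[i], f[i])
      params[[sprintf("dec%d_bn", i)]] <- bn_init(f[i])
      prev <- f[i]
    }
    params[["out_conv"]] <- conv_init(f[1], 1)
    structure(list(cfg = cfg, params = params, filters = f), class = "unet")
  })
}

#' @export
print.unet <- function(x, ...) {
  np <- sum(vapply(x$params, function(p) sum(lengths(lapply(p, length))) * 0 +
                     sum(vapply(p, length, integer(1))), numeric(1)))
  cat(sprintf("<unet> grid %d^3, filters %s, %d parameters\n",
              x$cfg$grid_size, paste(x$filters, collapse = "/"), np))
  invisible(x)
}

leaky_relu <- function(x, slope) pmax(x, 0) + slope * pmin(x, 0)

# Per-channel statistics over (spatial x batch). Arrays are (nx,ny,nz,C,B);
# reshaping to (nvox, C, B) lets channel sums come from one rowsum over a
# (nvox*C x B) -> per-channel fold.
bn_channel_sums <- function(v, nvox, C, B) {
  m <- matrix(v, nrow = nvox * C)              # columns = batch
  s <- rowSums(m)
  .colSums(matrix(s, nrow = nvox, ncol = C), nvox, C)
}

bn_forward <- function(x, p, training, momentum = 0.1, eps = 1e-5) {
  d <- dim(x)
  C <- d[4]; nvox <- prod(d[1:3]); B <- d[5]
  n_per <- nvox * B
  if (training) {
    mu <- bn_channel_sums(x, nvox, C, B) / n_per
    va <- bn_channel_sums(x * x, nvox, C, B) / n_per - mu^2
    va <- pmax(va, 0)
    p$run_mean <- (1 - momentum) * p$run_mean + momentum * mu
    p$run_var <- (1 - momentum) * p$run_var + momentum * va
  } else {
    mu <- p$run_mean; va <- p$run_var
  }
  invstd <- 1 / sqrt(va + eps)
  # column-expanded (per channel, recycled over batch) coefficient vectors
  a <- rep(p$gamma * invstd, each = nvox)      # length nvox*C, recycled over B
  b <- rep(p$beta - p$gamma * invstd * mu, each = nvox)
  y <- array(x * a + b, dim = d)
  list(y = y,
       cache = list(x = x, mu = mu, invstd = invstd, p = p,
                    nvox = nvox, C = C, B = B),
       p = p)
}

bn_backward <- function(dy, cache) {
  p <- cache$p; invstd <- cache$invstd; mu <- cache$mu
  nvox <- cache$nvox; C <- cache$C; B <- cache$B
  n_per <- nvox * B
  xhat <- (cache$x - rep(mu, each = nvox)) * rep(invstd, each = nvox)
  dbeta <- bn_channel_sums(dy, nvox, C, B)
  dgamma <- bn_channel_sums(dy * xhat, nvox, C, B)
  coef <- rep(p$gamma * invstd, each = nvox)
  dx <- coef * (dy - rep(dbeta / n_per, each = nvox) -
                  xhat * rep(dgamma / n_per, each = nvox))
  list(dx = array(dx, dim = dim(dy)), dgamma = dgamma, dbeta = dbeta)
}

concat_c <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, dim = c(da[1:3], da[4] + db[4], da[5]))
  nv <- prod(da[1:3])
  for (bb in seq_len(da[5])) {
    o0 <- (bb - 1) * nv * (da[4] + db[4])
    out[o0 + seq_len(nv * da[4])] <- a[(bb - 1) * nv * da[4] + seq_len(nv * da[4])]
    out[o0 + nv * da[4] + seq_len(nv * db[4])] <-
      b[(bb - 1) * nv * db[4] + seq_len(nv * db[4])]
  }
  out
}

split_c <- function(x, c1) {
  d <- dim(x)
  nv <- prod(d[1:3]); c2 <- d[4] - c1
  a <- array(0, dim = c(d[1:3], c1, d[5]))
  b <- array(0, dim = c(d[1:3], c2, d[5]))
  for (bb in seq_len(d[5])) {
    o0 <- (bb - 1) * nv * d[4]
    a[(bb - 1) * nv * c1 + seq_len(nv * c1)] <- x[o0 + seq_len(nv * c1)]
    b[(bb - 1) * nv * c2 + seq_len(nv * c2)] <- x[o0 + nv * c1 + seq_len(nv * c2)]
  }
  list(a, b)
}

# Full forward pass. training=TRUE uses batch statistics and dropout (masks
# drawn from R's RNG); returns the cache needed for backward.
unet_forward <- function(net, x, training = FALSE) {
  cfg <- net$cfg; P <- net$params
  cache <- list(x = x)
  h <- x
  skips <- list()
  for (i in seq_len(cfg$depth)) {
    for (j in 1:2) {
      cname <- sprintf("enc%d_conv%d", i, j)
      bname <- sprintf("enc%d_bn%d", i, j)
      xin <- h
      h <- .conv3d_fwd(xin, P[[cname]]$w, P[[cname]]$b)
      bn <- bn_forward(h, P[[bname]], training)
      P[[bname]] <- bn$p
      a <- leaky_relu(bn$y, cfg$leaky_slope)
      cache[[cname]] <- list(xin = xin)
      cache[[bname]] <- bn$cache
      cache[[sprintf("enc%d_act%d", i, j)]] <- bn$y   # pre-activation
      h <- a
    }
    skips[[i]] <- h
    mp <- .maxpool3d_fwd(h)
    cache[[sprintf("pool%d", i)]] <- list(idx = mp$idx, xdim = dim(h))
    h <- mp$y
    if (training && cfg$dropout > 0) {
      mask <- array((stats::runif(length(h)) >= cfg$dropout) / (1 - cfg$dropout),
                    dim = dim(h))
      cache[[sprintf("drop%d", i)]] <- mask
      h <- h * mask
    }
  }
  for (i in rev(seq_len(cfg$depth))) {
    up <- .upsample3d_fwd(h)
    cat_in <- concat_c(up, skips[[i]])
    cname <- sprintf("dec%d_conv", i)
    bname <- sprintf("dec%d_bn", i)
    h2 <- .conv3d_fwd(cat_in, P[[cname]]$w, P[[cname]]$b)
    bn <- bn_forward(h2, P[[bname]], training)
    P[[bname]] <- bn$p
    cache[[cname]] <- list(xin = cat_in, up_channels = dim(up)[4])
    cache[[bname]] <- bn$cache
    cache[[sprintf("dec%d_act", i)]] <- bn$y
    h <- pmax(bn$y, 0)                                  # plain ReLU in decoder
  }
  xin <- h
  logits <- .conv3d_fwd(xin, P[["out_conv"]]$w, P[["out_conv"]]$b)
  cache[["out_conv"]] <- list(xin = xin)
  y <- 1 / (1 + exp(-logits))
  cache$y <- y
  net$params <- P                                       # updated running stats
  list(y = y, cache = cache, net = net)
}

# Backward pass: dy is the gradient at the sigmoid output. Returns grads
# named like params.
unet_backward <- function(net, cache, dy) {
  cfg <- net$cfg; P <- net$params
  grads <- list()
  y <- cache$y
  g <- dy * y * (1 - y)                                 # through sigmoid
  cv <- .conv3d_bwd(cache[["out_conv"]]$xin, P[["out_conv"]]$w, g)
  grads[["out_conv"]] <- list(w = cv$dw, b = cv$db)
  g <- cv$dx
  for (i in seq_len(cfg$depth)) {                       # decoder, shallow->deep
    g <- g * (cache[[sprintf("dec%d_act", i)]] > 0)     # ReLU
    bb <- bn_backward(g, cache[[sprintf("dec%d_bn", i)]])
    grads[[sprintf("dec%d_bn", i)]] <- list(gamma = bb$dgamma, beta = bb$dbeta)
    cc <- cache[[sprintf("dec%d_conv", i)]]
    cv <- .conv3d_bwd(cc$xin, P[[sprintf("dec%d_conv", i)]]$w, bb$dx)
    grads[[sprintf("dec%d_conv", i)]] <- list(w = cv$dw, b = cv$db)
    parts <- split_c(cv$dx, cc$up_channels)
    g_skip <- parts[[2]]
    g_up <- .upsample3d_bwd(parts[[1]])
    # stash: gradient flowing into encoder skip i, and into deeper layer
    grads[[sprintf(".skip%d", i)]] <- g_skip
    g <- g_up
  }
  # encoder, deep->shallow; g currently flows into pool of deepest block
  for (i in rev(seq_len(cfg$depth))) {
    dmask <- cache[[sprintf("drop%d", i)]]
    if (!is.null(dmask)) g <- g * dmask
    pc <- cache[[sprintf("pool%d", i)]]
    g <- .maxpool3d_bwd(g, pc$idx, pc$xdim)
    g <- g + grads[[sprintf(".skip%d", i)]]
    grads[[sprintf(".skip%d", i)]] <- NULL
    for (j in 2:1) {
      pre <- cache[[sprintf("enc%d_act%d", i, j)]]
      g <- g * ((pre > 0) + cfg$leaky_slope * (pre <= 0))
      bb <- bn_backward(g, cache[[sprintf("enc%d_bn%d", i, j)]])
      grads[[sprintf("enc%d_bn%d", i, j)]] <- list(gamma = bb$dgamma, beta = bb$dbeta)
      cc <- cache[[sprintf("enc%d_conv%d", i, j)]]
      cv <- .conv3d_bwd(cc$xin, P[[sprintf("enc%d_conv%d", i, j)]]$w, bb$dx)
      grads[[sprintf("enc%d_conv%d", i, j)]] <- list(w = cv$dw, b = cv$db)
      g <- cv$dx
    }
  }
  grads
}
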