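#' Masked MSE + MAE loss
#'
#' The training loss: the mean over in-mask voxels of the squared error plus
#' the mean over in-mask voxels of the absolute error. Out-of-mask voxels do
#' not contribute.
#'
#' @param pred,gt numeric arrays of identical shape (any rank; a trailing
#'   batch dimension is allowed as long as `mask` broadcasts by recycling).
#' @param brain_mask binary array with the spatial shape of one sample.
#' @return Scalar loss.
#' @export
masked_loss <- function(pred, gt, brain_mask) {
  if (!identical(dim(pred), dim(gt))) stop("pred/gt shape mismatch")
  m <- as.logical(brain_mask > 0)
  if (!any(m)) stop("brain mask is empty")
  nrep <- length(pred) / length(brain_mask)
  if (nrep != floor(nrep)) stop("mask does not tile pred")
  msel <- rep(m, nrep)
  d <- pred[msel] - gt[msel]
  mean(d^2) + mean(abs(d))
}

# Gradient of masked_loss w.r.t. pred (same shape as pred).
masked_loss_grad <- function(pred, gt, brain_mask) {
  m <- rep(as.logical(brain_mask > 0), length(pred) / length(brain_mask))
  n <- sum(m)
  d <- pred - gt
  g <- (2 * d + sign(d)) / n
  g[!m] <- 0
  array(g, dim = dim(pred))
}

#' Split paired data into training and validation partitions
#'
#' Seed-deterministic shuffle; training size is `floor(fraction * N)`, the
#' partitions are disjoint and exhaustive.
#'
#' @param n number of pairs (or a list whose length is used).
#' @param fraction training fraction in (0, 1), default 0.8.
#' @param seed integer seed.
#' @return List with integer index vectors `train` and `val`.
#' @examples
#' split_dataset(1333)$train |> length()   # 1066
#' @export
split_dataset <- function(n, fraction = 0.8, seed = 1) {
  if (is.list(n)) n <- length(n)
  if (n < 2) stop("need at least two pairs to split")
  n_train <- floor(fraction * n)
  if (n_train < 1 || n_train >= n)
    stop("split fraction yields an empty partition")
  perm <- with_seed(seed, sample.int(n))
  list(train = sort(perm[seq_len(n_train)]), val = sort(perm[-seq_len(n_train)]))
}

flatten_params <- function(params) {
  out <- list()
  for (nm in names(params))
    for (f in names(params[[nm]]))
      if (f %in% c("w", "b", "gamma", "beta"))
        out[[paste(nm, f, sep = ".")]] <- params[[nm]][[f]]
  out
}

# Assemble a batch input array (d, d, d, 2, B): channel 1 lesion, channel 2
# the fixed template.
make_batch <- function(lesions, template, idx) {
  d <- dim(template)
  B <- length(idx)
  x <- array(0, dim = c(d, 2, B))
  nv <- prod(d)
  for (k in seq_along(idx)) {
    o <- (k - 1) * 2 * nv
    x[o + seq_len(nv)] <- lesions[[idx[k]]]
    x[o + nv + seq_len(nv)] <- template
  }
  x
}

stack_targets <- function(targets, idx) {
  d <- dim(targets[[1]])
  y <- array(0, dim = c(d, 1, length(idx)))
  nv <- prod(d)
  for (k in seq_along(idx)) y[(k - 1) * nv + seq_len(nv)] <- targets[[idx[k]]]
  y
}

adam_step <- function(state, params, grads, lr, wd, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    for (f in names(params[[nm]])) {
      if (!f %in% c("w", "b", "gamma", "beta")) next
      key <- paste(nm, f, sep = ".")
      g <- grads[[nm]][[f]]
      if (wd > 0 && f %in% c("w")) g <- g + wd * params[[nm]][[f]]
      if (is.null(state$m[[key]])) {
        state$m[[key]] <- g * 0
        state$v[[key]] <- g * 0
      }
      state$m[[key]] <- 0.9 * state$m[[key]] + 0.1 * g
      state$v[[key]] <- 0.999 * state$v[[key]] + 0.001 * g^2
      mhat <- state$m[[key]] / bc1
      vhat <- state$v[[key]] / bc2
      params[[nm]][[f]] <- params[[nm]][[f]] - lr * mhat / (sqrt(vhat) + eps)
    }
  }
  list(state = state, params = params)
}

#' Train the U-Net on lesion/disconnectome pairs
#'
#' Minimizes the masked MSE + MAE loss with Adam (weight decay on
#' convolution weights). The second input channel is the fixed average
#' disconnectome template for every sample. Training stops at `max_epochs`
#' or once validation loss has not improved for `early_stop_patience`
#' epochs; the returned model carries the weights of the best validation
#' epoch. Fully deterministic for a fixed `cfg$seed`.
#'
#' @param net a [build_unet()] model.
#' @param pairs list of `list(lesion = <3-D array>, target = <3-D array>)`
#'   on the model grid.
#' @param brain_mask binary 3-D array on the model grid.
#' @param template 3-D array, the fixed second channel ([average_template()]).
#' @param cfg a [train_config()].
#' @param split optional precomputed split (from [split_dataset()]); by
#'   default an 80/20 split with the config's seed.
#' @param verbose print per-epoch losses.
#' @return List with `net` (trained, best-epoch weights) and `history` (a
#'   `loss_record` data.frame: epoch, train_loss, val_loss; attribute
#'   `best_epoch`).
#' @export
train_model <- function(net, pairs, brain_mask, template, cfg = train_config(),
                        split = NULL, verbose = FALSE) {
  if (length(pairs) < 2) stop("need at least two pairs")
  d <- dim(template)
  if (is.null(split))
    split <- split_dataset(length(pairs), cfg$split_fraction, cfg$seed)
  lesions <- lapply(pairs, `[[`, "lesion")
  targets <- lapply(pairs, `[[`, "target")
  mask5 <- brain_mask
  state <- list(t = 0, m = list(), v = list())
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0))
  best_val <- Inf; best_params <- net$params; best_epoch <- 0L
  wait <- 0L

  eval_loss <- function(net, idx) {
    tot <- 0; nb <- 0
    for (start in seq(1, length(idx), by = cfg$batch_size)) {
      bi <- idx[start:min(start + cfg$batch_size - 1, length(idx))]
      x <- make_batch(lesions, template, bi)
      y <- stack_targets(targets, bi)
      fw <- unet_forward(net, x, training = FALSE)
      tot <- tot + masked_loss(fw$y, y, mask5) * length(bi)
      nb <- nb + length(bi)
    }
    tot / nb
  }

  set.seed(cfg$seed)
  for (epoch in seq_len(cfg$max_epochs)) {
    ord <- split$train[sample.int(length(split$train))]
    ep_loss <- 0; ep_n <- 0
    for (start in seq(1, length(ord), by = cfg$batch_size)) {
      bi <- ord[start:min(start + cfg$batch_size - 1, length(ord))]
      x <- make_batch(lesions, template, bi)
      y <- stack_targets(targets, bi)
      fw <- unet_forward(net, x, training = TRUE)
      net <- fw$net
      loss <- masked_loss(fw$y, y, mask5)
      if (!is.finite(loss))
        stop(sprintf("non-finite training loss at epoch %d", epoch))
      dy <- masked_loss_grad(fw$y, y, mask5)
      grads <- unet_backward(net, fw$cache, dy)
      upd <- adam_step(state, net$params, grads, cfg$learning_rate,
                       cfg$weight_decay)
      state <- upd$state
      net$params <- upd$params
      ep_loss <- ep_loss + loss * length(bi); ep_n <- ep_n + length(bi)
    }
    val <- eval_loss(net, split$val)
    if (!is.finite(val)) stop(sprintf("non-finite validation loss at epoch %d", epoch))
    history <- rbind(history, data.frame(epoch = epoch,
                                         train_loss = ep_loss / ep_n,
                                         val_loss = val))
    if (verbose)
      message(sprintf("epoch %3d  train %.5f  val %.5f", epoch,
                      ep_loss / ep_n, val))
    if (val < best_val - 1e-12) {
      best_val <- val; best_params <- net$params; best_epoch <- epoch
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= cfg$early_stop_patience) break
    }
  }
  net$params <- best_params
  attr(history, "best_epoch") <- best_epoch
  class(history) <- c("loss_record", class(history))
  list(net = net, history = history, split = split)
}

#' Resize transform between a source grid and the cubic model grid
#'
#' Maps with half-voxel-centre alignment: target voxel `t` samples source
#' coordinate `(t + 0.5) * S/T - 0.5`. Interpolation is nearest-neighbour
#' for binary masks and trilinear for float volumes; the inverse maps back
#' to the recorded source shape (shape-exact always; nearest-neighbour
#' round-trips are value-exact when the target is at least as large as the
#' source on every axis).
#'
#' @param source_shape integer length-3 source dimensions.
#' @param target_shape integer length-3 target dimensions.
#' @return A `resize_transform` object.
#' @export
resize_transform <- function(source_shape, target_shape) {
  structure(list(source = as.integer(source_shape),
                 target = as.integer(target_shape)),
            class = "resize_transform")
}

resize_volume <- function(data, from_shape, to_shape, method = c("trilinear", "nearest")) {
  method <- match.arg(method)
  if (!identical(as.integer(dim(data)), as.integer(from_shape)))
    stop("resize: input shape mismatch")
  if (identical(as.integer(from_shape), as.integer(to_shape))) return(data)
  coord <- function(n_to, n_from) {
    s <- (seq_len(n_to) - 0.5) * n_from / n_to - 0.5
    pmin(pmax(s, 0), n_from - 1)
  }
  sx <- coord(to_shape[1], from_shape[1])
  sy <- coord(to_shape[2], from_shape[2])
  sz <- coord(to_shape[3], from_shape[3])
  if (method == "nearest") {
    ix <- pmin(pmax(round(sx), 0), from_shape[1] - 1) + 1
    iy <- pmin(pmax(round(sy), 0), from_shape[2] - 1) + 1
    iz <- pmin(pmax(round(sz), 0), from_shape[3] - 1) + 1
    return(data[ix, iy, iz, drop = FALSE])
  }
  x0 <- floor(sx); y0 <- floor(sy); z0 <- floor(sz)
  wx <- sx - x0; wy <- sy - y0; wz <- sz - z0
  x1 <- pmin(x0 + 1, from_shape[1] - 1); y1 <- pmin(y0 + 1, from_shape[2] - 1)
  z1 <- pmin(z0 + 1, from_shape[3] - 1)
  # vectorized trilinear gather via outer-product index grids
  IX0 <- x0 + 1; IX1 <- x1 + 1
  arr <- function(ax, ay, az) data[ax, ay, az, drop = FALSE]
  WX <- array(wx, dim = to_shape)
  WY <- array(rep(wy, each = to_shape[1]), dim = to_shape)
  WZ <- array(rep(wz, each = to_shape[1] * to_shape[2]), dim = to_shape)
  out <- (1 - WZ) * ((1 - WY) * ((1 - WX) * arr(IX0, y0 + 1, z0 + 1) +
                                   WX * arr(IX1, y0 + 1, z0 + 1)) +
                       WY * ((1 - WX) * arr(IX0, y1 + 1, z0 + 1) +
                               WX * arr(IX1, y1 + 1, z0 + 1))) +
    WZ * ((1 - WY) * ((1 - WX) * arr(IX0, y0 + 1, z1 + 1) +
                        WX * arr(IX1, y0 + 1, z1 + 1)) +
            WY * ((1 - WX) * arr(IX0, y1 + 1, z1 + 1) +
                    WX * arr(IX1, y1 + 1, z1 + 1)))
  out
}

#' Apply / invert a resize transform
#'
#' @param rt a [resize_transform()].
#' @param data 3-D array on the source (apply) or target (invert) grid.
#' @param kind `"mask"` (nearest-neighbour) or `"float"` (trilinear).
#' @return Resized 3-D array.
#' @export
apply_resize <- function(rt, data, kind = c("float", "mask")) {
  kind <- match.arg(kind)
  resize_volume(data, rt$source, rt$target,
                if (kind == "mask") "nearest" else "trilinear")
}

#' @rdname apply_resize
#' @export
invert_resize <- function(rt, data, kind = c("float", "mask")) {
  kind <- match.arg(kind)
  resize_volume(data, rt$target, rt$source,
                if (kind == "mask") "nearest" else "trilinear")
}

#' Predict a deep-disconnectome from a lesion mask
#'
#' Resizes the lesion (nearest-neighbour) and template (trilinear) to the
#' model grid, runs the forward pass in evaluation mode, inverse-resizes the
#' output to the source grid, and zeroes voxels outside the brain mask.
#'
#' @param net trained [build_unet()] model.
#' @param lesion a `lesion_mask` on the source grid.
#' @param template 3-D array on the source grid.
#' @param brain_mask binary 3-D array on the source grid.
#' @param rt a [resize_transform()] from the source grid to the model grid
#'   (identity if omitted and shapes already match).
#' @return A `disconnectome` on the source grid with values in \[0, 1\].
#' @export
predict_deep_disconnectome <- function(net, lesion, template, brain_mask,
                                       rt = NULL) {
  src_shape <- lesion$grid$shape
  model_shape <- rep(net$cfg$grid_size, 3L)
  if (is.null(rt)) rt <- resize_transform(src_shape, model_shape)
  if (!identical(rt$source, src_shape))
    stop("lesion shape does not match the resize transform source")
  les_m <- apply_resize(rt, lesion$data, "mask")
  tpl_m <- apply_resize(rt, template, "float")
  x <- array(0, dim = c(model_shape, 2, 1))
  nv <- prod(model_shape)
  x[seq_len(nv)] <- les_m
  x[nv + seq_len(nv)] <- tpl_m
  fw <- unet_forward(net, x, training = FALSE)
  out <- array(fw$y[seq_len(nv)], dim = model_shape)
  out <- invert_resize(rt, out, "float")
  out <- out * (brain_mask > 0)
  new_disconnectome(lesion$grid, pmin(pmax(out, 0), 1),
                    n_subjects = NA_integer_)
}

#' Goodness of fit between a predicted and a reference map
#'
#' The squared Pearson correlation across in-mask voxels (not
#' 1 - SS_res/SS_tot, which differs for biased predictors). Returns `NaN`
#' with a warning when either map has zero in-mask variance.
#'
#' @param pred,gt 3-D arrays (or `disconnectome` objects).
#' @param brain_mask binary 3-D array.
#' @return Scalar squared Pearson correlation.
#' @export
goodness_of_fit <- function(pred, gt, brain_mask) {
  a <- if (inherits(pred, "disconnectome")) pred$data else pred
  b <- if (inherits(gt, "disconnectome")) gt$data else gt
  m <- as.logical(brain_mask > 0)
  x <- a[m]; y <- b[m]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero variance in one of the maps; R^2 undefined")
    return(NaN)
  }
  stats::cor(x, y)^2
}

#' Save / load a trained model
#'
#' Weights go to a binary RDS checkpoint, the configuration to a JSON
#' sidecar, and (when given) the training history to CSV.
#'
#' @param trained result of [train_model()] (or a bare `unet`).
#' @param dir output directory.
#' @return The directory, invisibly.
#' @export
save_model <- function(trained, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  net <- if (inherits(trained, "unet")) trained else trained$net
  saveRDS(net$params, file.path(dir, "weights.rds"))
  cfg <- net$cfg
  jsonlite::write_json(list(grid_size = cfg$grid_size,
                            base_filters = cfg$base_filters,
                            depth = cfg$depth, in_channels = cfg$in_channels,
                            dropout = cfg$dropout,
                            leaky_slope = cfg$leaky_slope,
                            voxel_size = cfg$model_grid$voxel_size),
                       file.path(dir, "config.json"), auto_unbox = TRUE)
  if (!inherits(trained, "unet") && !is.null(trained$history))
    utils::write.csv(as.data.frame(trained$history),
                     file.path(dir, "history.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname save_model
#' @export
load_model <- function(dir) {
  cfgj <- jsonlite::read_json(file.path(dir, "config.json"), simplifyVector = TRUE)
  cfg <- model_config(grid_size = cfgj$grid_size, base_filters = cfgj$base_filters,
                      depth = cfgj$depth, in_channels = cfgj$in_channels,
                      dropout = cfgj$dropout, leaky_slope = cfgj$leaky_slope,
                      voxel_size = cfgj$voxel_size)
  net <- build_unet(cfg, seed = 1)
  net$params <- readRDS(file.path(dir, "weights.rds"))
  net
}
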