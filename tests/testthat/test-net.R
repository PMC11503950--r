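test_that("network output has the right shape and sigmoid range", {
  cfg <- model_config(grid_size = 16, base_filters = 4, voxel_size = 1)
  net <- build_unet(cfg, seed = 1)
  set.seed(2)
  x <- array(stats::runif(16^3 * 2 * 2), dim = c(16, 16, 16, 2, 2))
  y <- deepdisco:::unet_forward(net, x, training = FALSE)$y
  expect_identical(dim(y), c(16L, 16L, 16L, 1L, 2L))
  expect_true(all(y > 0 & y < 1))
  # grid not divisible by 2^depth is rejected
  expect_error(model_config(grid_size = 20, base_filters = 4), "divisible")
  # filters double per encoder block
  expect_identical(net$filters, c(4L, 8L, 16L))
  expect_identical(dim(net$params$enc2_conv1$w)[4:5], c(4L, 8L))
  expect_identical(dim(net$params$enc3_conv2$w)[4:5], c(16L, 16L))
  # decoder mirrors the encoder widths after concatenation
  expect_identical(dim(net$params$dec3_conv$w)[4:5], c(32L, 16L))
  expect_identical(dim(net$params$dec1_conv$w)[4:5], c(12L, 4L))
})

test_that("max-pooling halves and upsampling doubles the spatial grid", {
  set.seed(3)
  x <- array(stats::rnorm(8^3 * 2 * 1), dim = c(8, 8, 8, 2, 1))
  p <- deepdisco:::.maxpool3d_fwd(x)
  expect_identical(dim(p$y), c(4L, 4L, 4L, 2L, 1L))
  u <- deepdisco:::.upsample3d_fwd(p$y)
  expect_identical(dim(u), c(8L, 8L, 8L, 2L, 1L))
  # pooling picks the block maximum
  expect_equal(p$y[1, 1, 1, 1, 1], max(x[1:2, 1:2, 1:2, 1, 1]))
})

test_that("masked loss matches its closed form and a two-pass reference", {
  g <- tiny_grid(8)
  mask <- make_brain_mask(g, 1)
  a <- array(stats::runif(512), dim = c(8, 8, 8))
  expect_equal(masked_loss(a, a, mask), 0)
  # constant offset of 0.5 in-mask: MSE 0.25 + MAE 0.5
  b <- a + 0.5
  expect_equal(masked_loss(b, a, mask), 0.75)
  # random tensors match an explicit two-pass computation
  set.seed(7)
  p <- array(stats::runif(512), dim = c(8, 8, 8))
  q <- array(stats::runif(512), dim = c(8, 8, 8))
  sel <- which(mask > 0)
  ref_mse <- sum((p[sel] - q[sel])^2) / length(sel)
  ref_mae <- sum(abs(p[sel] - q[sel])) / length(sel)
  expect_equal(masked_loss(p, q, mask), ref_mse + ref_mae, tolerance = 1e-12)
  expect_gte(ref_mse, 0); expect_gte(ref_mae, 0)
  expect_error(masked_loss(p, q, mask * 0), "empty")
})

test_that("dataset splitting follows the floor rule deterministically", {
  s <- split_dataset(1333, 0.8, seed = 4)
  expect_length(s$train, 1066)
  expect_length(s$val, 267)
  expect_length(intersect(s$train, s$val), 0)
  expect_setequal(c(s$train, s$val), 1:1333)
  s10 <- split_dataset(10, 0.8, seed = 1)
  expect_length(s10$train, 8)
  expect_length(s10$val, 2)
  expect_identical(split_dataset(50, 0.8, seed = 9),
                   split_dataset(50, 0.8, seed = 9))
  expect_error(split_dataset(2, 0.1), "empty")
})

test_that("analytic gradients match finite differences through every block", {
  cfg <- model_config(grid_size = 8, base_filters = 2, voxel_size = 1,
                      dropout = 0)
  net <- build_unet(cfg, seed = 2)
  g <- tiny_grid(8)
  mask <- make_brain_mask(g, 1)
  set.seed(1)
  x <- array(stats::runif(8^3 * 2 * 2), dim = c(8, 8, 8, 2, 2))
  y <- array(stats::runif(8^3 * 2), dim = c(8, 8, 8, 1, 2))
  fw <- deepdisco:::unet_forward(net, x, training = TRUE)
  dy <- deepdisco:::masked_loss_grad(fw$y, y, mask)
  grads <- deepdisco:::unet_backward(net, fw$cache, dy)
  eps <- 1e-5
  for (spot in list(c("enc1_conv1", "w", 5), c("enc2_conv2", "w", 40),
                    c("enc3_conv1", "b", 2), c("dec3_conv", "w", 25),
                    c("dec1_conv", "w", 2), c("out_conv", "w", 3),
                    c("enc1_bn1", "gamma", 1), c("dec2_bn", "beta", 2))) {
    layer <- spot[1]; field <- spot[2]; idx <- as.integer(spot[3])
    p <- net$params; n2 <- net
    p[[layer]][[field]][idx] <- p[[layer]][[field]][idx] + eps
    n2$params <- p
    lp <- masked_loss(deepdisco:::unet_forward(n2, x, TRUE)$y, y, mask)
    p[[layer]][[field]][idx] <- p[[layer]][[field]][idx] - 2 * eps
    n2$params <- p
    lm <- masked_loss(deepdisco:::unet_forward(n2, x, TRUE)$y, y, mask)
    num <- (lp - lm) / (2 * eps)
    ana <- grads[[layer]][[field]][idx]
    expect_equal(ana, num, tolerance = 1e-4,
                 label = paste(layer, field, idx))
  }
})

test_that("early stopping obeys the patience rule and restores best weights", {
  # two pairs, patience 1: if validation never improves after epoch 1,
  # training stops at epoch 2
  g <- tiny_grid(8)
  mask <- make_brain_mask(g, 1)
  set.seed(5)
  pairs <- lapply(1:4, function(i) {
    les <- array(as.numeric(stats::runif(512) < 0.1), dim = c(8, 8, 8))
    list(lesion = les, target = array(0.3, dim = c(8, 8, 8)) * mask)
  })
  tpl <- average_template(lapply(pairs, `[[`, "target"))
  cfg <- model_config(8, 2, voxel_size = 1)
  net <- build_unet(cfg, seed = 1)
  tc <- train_config(batch_size = 2, learning_rate = 10,  # diverging LR
                     max_epochs = 30, early_stop_patience = 1, seed = 2)
  tr <- train_model(net, pairs, mask, tpl, tc)
  h <- tr$history
  best <- attr(h, "best_epoch")
  stopped <- nrow(h)
  expect_lte(stopped, 30)
  expect_equal(stopped, best + 1)               # one non-improving epoch
  expect_equal(h$val_loss[best], min(h$val_loss))
})

test_that("training is deterministic and can overfit a single pair", {
  g <- tiny_grid(8)
  mask <- make_brain_mask(g, 1)
  w <- tiny_world(8, n_bundles = 2, n_subjects = 2, per_bundle = 3, seed = 8)
  les <- make_lesion(w$mask, w$grid, c(2, 3), seed = 17)
  d <- compute_disconnectome(les, w$tracts, brain_mask = w$mask)
  pairs <- list(list(lesion = les$data, target = d$data),
                list(lesion = les$data, target = d$data))
  tpl <- d$data
  cfg <- model_config(8, 2, voxel_size = 1)
  tc <- train_config(batch_size = 1, max_epochs = 15, early_stop_patience = 15,
                     seed = 3)
  tr1 <- train_model(build_unet(cfg, seed = 4), pairs, w$mask, tpl, tc)
  tr2 <- train_model(build_unet(cfg, seed = 4), pairs, w$mask, tpl, tc)
  expect_identical(tr1$history$train_loss, tr2$history$train_loss)
  expect_identical(tr1$history$val_loss, tr2$history$val_loss)
  # a longer unregularized run overfits the pair almost perfectly
  cfg0 <- model_config(8, 2, voxel_size = 1, dropout = 0)
  tc2 <- train_config(batch_size = 1, learning_rate = 3e-3, max_epochs = 200,
                      early_stop_patience = 200, seed = 3)
  tr3 <- train_model(build_unet(cfg0, seed = 4), pairs, w$mask, tpl, tc2)
  expect_lt(utils::tail(tr3$history$train_loss, 1), 0.02)
})

test_that("goodness of fit is squared Pearson with affine invariance", {
  g <- tiny_grid(8)
  mask <- make_brain_mask(g, 1)
  set.seed(9)
  a <- array(stats::runif(512), dim = c(8, 8, 8))
  expect_equal(goodness_of_fit(a, a, mask), 1)
  expect_equal(goodness_of_fit(2 * a + 3, a, mask), 1)
  b <- array(stats::runif(512), dim = c(8, 8, 8))
  sel <- which(mask > 0)
  x <- a[sel]; y <- b[sel]
  ref <- (sum((x - mean(x)) * (y - mean(y))) /
            sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2)))^2
  expect_equal(goodness_of_fit(a, b, mask), ref, tolerance = 1e-12)
  expect_warning(r <- goodness_of_fit(a * 0, b, mask), "variance")
  expect_true(is.nan(r))
})

test_that("resize transforms are shape-invertible and mask-exact upscale", {
  rt <- resize_transform(c(11, 13, 11), c(16, 16, 16))
  set.seed(10)
  les <- array(as.numeric(stats::runif(11 * 13 * 11) < 0.2), dim = c(11, 13, 11))
  up <- apply_resize(rt, les, "mask")
  expect_identical(dim(up), c(16L, 16L, 16L))
  back <- invert_resize(rt, up, "mask")
  expect_identical(dim(back), c(11L, 13L, 11L))
  expect_identical(back, les)                    # value-exact: target >= source
  # floats survive with bounded interpolation error
  f <- array(stats::runif(11 * 13 * 11), dim = c(11, 13, 11))
  fb <- invert_resize(rt, apply_resize(rt, f, "float"), "float")
  expect_lt(max(abs(fb - f)), 0.5)
  expect_error(apply_resize(rt, array(0, dim = c(5, 5, 5)), "mask"), "shape")
})

test_that("deep-disconnectome predictions are masked and in range", {
  w <- tiny_world(16, n_bundles = 2, n_subjects = 2, seed = 12)
  les <- make_lesion(w$mask, w$grid, c(2, 3), seed = 1)
  d <- compute_disconnectome(les, w$tracts, brain_mask = w$mask)
  net <- build_unet(model_config(16, 2, voxel_size = 1), seed = 1)
  pred <- predict_deep_disconnectome(net, les, d$data, w$mask)
  expect_true(all(pred$data >= 0 & pred$data <= 1))
  expect_true(all(pred$data[w$mask == 0] == 0))
  expect_identical(dim(pred$data), dim(les$data))
})

test_that("models round-trip through the checkpoint directory", {
  dir <- file.path(tempdir(), "mdl")
  net <- build_unet(model_config(8, 2, voxel_size = 1), seed = 6)
  save_model(net, dir)
  net2 <- load_model(dir)
  expect_equal(net2$params, net$params)
  expect_equal(net2$cfg$grid_size, 8L)
  set.seed(3)
  x <- array(stats::runif(8^3 * 2), dim = c(8, 8, 8, 2, 1))
  expect_identical(deepdisco:::unet_forward(net, x, FALSE)$y,
                   deepdisco:::unet_forward(net2, x, FALSE)$y)
})

test_that("training beats the best constant predictor on held-out data", {
  w <- tiny_world(16, n_bundles = 4, n_subjects = 4, per_bundle = 8,
                  jitter_sd = 0.5, seed = 27)
  lesions <- lapply(1:32, function(i) make_lesion(w$mask, w$grid, c(2, 4),
                                                  seed = 8000 + i))
  oracle <- lapply(lesions, function(l)
    compute_disconnectome(l, brain_mask = w$mask, cache = w$cache))
  tpl <- average_template(oracle)
  pairs <- lapply(1:32, function(i) list(lesion = lesions[[i]]$data,
                                         target = oracle[[i]]$data))
  # a faster learning rate keeps this sanity run short; the standard
  # recipe reaches the same point over many more epochs
  tc <- train_config(learning_rate = 2e-3, max_epochs = 20,
                     early_stop_patience = 20, seed = 2)
  tr <- train_model(build_unet(model_config(16, 4, voxel_size = 2), seed = 1),
                    pairs, w$mask, tpl, tc)
  # best constant predictor: the in-mask mean of the training targets
  sel <- which(w$mask > 0)
  cst <- mean(vapply(tr$split$train, function(i) mean(oracle[[i]]$data[sel]),
                     numeric(1)))
  cst_loss <- mean(vapply(tr$split$val, function(i) {
    gt <- oracle[[i]]$data[sel]
    mean((cst - gt)^2) + mean(abs(cst - gt))
  }, numeric(1)))
  expect_lt(min(tr$history$val_loss), cst_loss)
})
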