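# Shared morphospace fixture: two geometrically distinct groups of
# disconnectomes (lesions confined to opposite ends of the brain), so the
# embedding has known cluster structure.
local_ms_fixture <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    w <- tiny_world(16, n_bundles = 4, n_subjects = 4, per_bundle = 6,
                    jitter_sd = 0.4, seed = 19)
    # bundle-A-only vs bundle-B-only disconnection patterns: the average
    # over a random subject subset of the union of traversals of one
    # bundle's streamlines
    bundle_map <- function(bundle_id, k) {
      set.seed(700 + k)
      subjects <- sample(seq_along(w$tracts), 3)
      acc <- array(0, dim = w$grid$shape)
      for (s in subjects) {
        sel <- which(w$cache$bundle_of[[s]] == bundle_id)
        sel <- sample(sel, max(2, length(sel) - 2))
        vis <- array(0, dim = w$grid$shape)
        vis[unique(unlist(w$cache$trav[[s]][sel]))] <- 1
        acc <- acc + vis
      }
      acc / 3
    }
    grpA <- lapply(1:12, function(k) bundle_map("bundle01", k))
    grpB <- lapply(13:24, function(k) bundle_map("bundle02", k))
    mat <- vectorize_maps(c(grpA, grpB), w$mask)
    ms <- fit_morphospace(mat, n_neighbors = 8, seed = 5)
    cache <<- list(w = w, mat = mat, ms = ms, n_a = 12, n_b = 12)
    cache
  }
})

test_that("vectorization uses a fixed voxel order and round-trips", {
  w <- tiny_world(10, n_subjects = 2, seed = 2)
  les <- make_lesion(w$mask, w$grid, c(2, 3), seed = 4)
  d <- compute_disconnectome(les, brain_mask = w$mask, cache = w$cache)
  zero <- array(0, dim = w$grid$shape)
  M <- vectorize_maps(list(zero, d), w$mask)
  expect_equal(M[1, ], rep(0, sum(w$mask)))
  # column count equals an independent voxel count
  cnt <- 0
  for (v in seq_along(w$mask)) if (w$mask[v] > 0) cnt <- cnt + 1
  expect_equal(ncol(M), cnt)
  # round trip restores the in-mask volume exactly
  back <- devectorize_map(M[2, ], w$mask)
  expect_identical(back, d$data * (w$mask > 0))
  expect_error(vectorize_maps(list(array(0, dim = c(9, 10, 10))), w$mask),
               "mismatch")
})

test_that("the fitted morphospace separates known clusters deterministically", {
  fx <- local_ms_fixture()
  co <- fx$ms$ref_coords
  a <- co[seq_len(fx$n_a), ]; b <- co[fx$n_a + seq_len(fx$n_b), ]
  centroid_gap <- sqrt(sum((colMeans(a) - colMeans(b))^2))
  within <- mean(c(sqrt(rowSums(sweep(a, 2, colMeans(a))^2)),
                   sqrt(rowSums(sweep(b, 2, colMeans(b))^2))))
  expect_gt(centroid_gap, within)
  # determinism of the fit
  ms2 <- fit_morphospace(fx$mat, n_neighbors = 8, seed = 5)
  expect_equal(ms2$ref_coords, fx$ms$ref_coords)
  # raster covers all reference points
  r <- fx$ms$raster
  expect_true(all(co[, 1] >= r$xmin & co[, 1] <= r$xmax))
  expect_true(all(co[, 2] >= r$ymin & co[, 2] <= r$ymax))
  expect_error(fit_morphospace(fx$mat[1:5, ], n_neighbors = 8), "n_neighbors")
})

test_that("new maps embed near their reference twins without refitting", {
  fx <- local_ms_fixture()
  co <- fx$ms$ref_coords
  emb <- embed_new(fx$ms, fx$mat[c(1, 15), , drop = FALSE])
  expect_identical(dim(emb), c(2L, 2L))
  # a copy of a reference row lands within the within-cluster spread
  spread <- max(stats::dist(co[1:12, ]))
  expect_lt(sqrt(sum((emb[1, ] - co[1, ])^2)), spread)
  expect_lt(sqrt(sum((emb[2, ] - co[15, ])^2)),
            max(stats::dist(co[13:24, ])))
  # empty input, repeated calls
  expect_identical(nrow(embed_new(fx$ms, fx$mat[0, , drop = FALSE])), 0L)
  expect_identical(embed_new(fx$ms, fx$mat[3, , drop = FALSE]),
                   embed_new(fx$ms, fx$mat[3, , drop = FALSE]))
})

test_that("localisation maps are smoothed probability images", {
  fx <- local_ms_fixture()
  co <- fx$ms$ref_coords[1, ]
  lm <- localisation_map(co, fx$ms)
  expect_equal(sum(lm), 1, tolerance = 1e-9)
  expect_true(all(lm >= 0))
  # argmax sits at the containing pixel
  px <- deepdisco:::pixel_of(co, fx$ms$raster)
  am <- which(lm == max(lm), arr.ind = TRUE)[1, ]
  expect_equal(unname(am), c(px$ix + 1, px$iy + 1))
  # coincident patients give identical maps
  expect_identical(localisation_map(co, fx$ms), lm)
  # out-of-extent coordinates clamp with a warning
  expect_warning(localisation_map(c(fx$ms$raster$xmax + 10, co[2]), fx$ms),
                 "clamped")
})

test_that("pixel-wise correlation matches the Pearson formula", {
  fx <- local_ms_fixture()
  set.seed(6)
  pts <- fx$ms$ref_coords[c(1, 5, 14, 20), ]
  maps <- lapply(seq_len(4), function(i) localisation_map(pts[i, ], fx$ms))
  scores <- c(2.5, 1.0, 4.0, 3.5)
  cm <- pixelwise_correlation(maps, scores)
  expect_true(all(abs(cm[!is.na(cm)]) <= 1 + 1e-12))
  # hand-computed Pearson at a few pixels
  for (pix in c(200, 1000, 2050)) {
    v <- sapply(maps, function(m) m[pix])
    ref <- if (stats::sd(v) == 0) NA_real_ else stats::cor(v, scores)
    expect_equal(cm[pix], ref, tolerance = 1e-12)
  }
  # scores equal to the patients' values at a pixel give R = 1 there
  pix0 <- which.max(maps[[1]])
  v0 <- sapply(maps, function(m) m[pix0])
  cm0 <- pixelwise_correlation(maps, v0)
  expect_equal(cm0[pix0], 1, tolerance = 1e-9)
  expect_error(pixelwise_correlation(maps[1:2], scores[1:2]), "at least 3")
  expect_error(pixelwise_correlation(maps, rep(1, 4)), "constant")
})

test_that("territory extraction ranks 8-connected clusters by summed |R|", {
  # uniform |R| = 0.1: nothing survives
  flat <- matrix(0.1, 16, 16)
  expect_length(extract_territories(flat)$clusters, 0)
  # single blob of |R| = 0.5
  m <- matrix(0, 16, 16)
  m[4:6, 4:6] <- 0.5
  ts <- extract_territories(m)
  expect_length(ts$clusters, 1)
  expect_setequal(ts$clusters[[1]]$pixels, which(m > 0.2))
  expect_equal(ts$clusters[[1]]$informativeness, 9 * 0.5)
  # negative correlations count via |R|
  ts_neg <- extract_territories(-m)
  expect_setequal(ts_neg$clusters[[1]]$pixels, which(m > 0.2))
  expect_length(extract_territories(-m, tails = "positive")$clusters, 0)
  # diagonal touching pixels are one 8-connected cluster
  dg <- matrix(0, 8, 8)
  dg[2, 2] <- 0.5; dg[3, 3] <- 0.5
  expect_length(extract_territories(dg)$clusters, 1)
  # five blobs: top 3 by summed |R|, verified by exhaustive ranking
  m5 <- matrix(0, 20, 20)
  vals <- c(0.9, 0.3, 0.6, 0.25, 0.45)
  at <- list(c(2, 2), c(2, 10), c(10, 2), c(10, 10), c(16, 16))
  sizes <- c(1, 4, 2, 6, 3)
  sums <- numeric(5)
  for (k in 1:5) {
    i <- at[[k]][1]; j <- at[[k]][2]
    n <- sizes[k]
    m5[i + seq_len(n) - 1, j] <- vals[k]
    sums[k] <- n * vals[k]
  }
  ts5 <- extract_territories(m5, top_k = 3)
  got <- sort(sapply(ts5$clusters, `[[`, "informativeness"), decreasing = TRUE)
  expect_equal(got, sort(sums, decreasing = TRUE)[1:3], tolerance = 1e-12)
})

test_that("score models are exact for linear targets and reproducible", {
  fx <- local_ms_fixture()
  co <- fx$ms$ref_coords
  maps <- lapply(seq_len(nrow(co)), function(i) localisation_map(co[i, ], fx$ms))
  # a synthetic score linear in localisation contrast between the clusters
  scores <- c(rep(1, fx$n_a), rep(3, fx$n_b)) + 0.01 * seq_len(24)
  corr <- pixelwise_correlation(maps, scores)
  terr <- extract_territories(corr)
  expect_gt(length(terr$clusters), 0)
  model <- fit_score_model(maps, terr, scores, n_components = 3)
  # training predictions equal OLS fitted values
  expect_equal(predict_scores(model, maps), model$fitted, tolerance = 1e-9)
  # identical patient gives identical prediction
  expect_equal(predict_scores(model, maps[3]), model$fitted[3], tolerance = 1e-9)
  # scores exactly linear in the first component recover R^2 = 1
  px <- deepdisco:::territory_pixels(terr)
  X <- t(vapply(maps, function(m) as.vector(m)[px], numeric(length(px))))
  pc <- stats::prcomp(sweep(X, 2, colMeans(X)), center = FALSE)
  lin <- 2 + 0.5 * pc$x[, 1]
  mlin <- fit_score_model(maps, terr, lin, n_components = 3)
  expect_equal(mlin$fitted, unname(lin), tolerance = 1e-6)
  # component truncation warns when patients are too few
  expect_warning(fit_score_model(maps[1:5], terr, scores[1:5],
                                 n_components = 4), "truncated")
  # scripted matrix-multiplication reference for predictions
  W <- sweep(X, 2, model$center) %*% model$rotation
  ref <- as.vector(cbind(1, W) %*% model$coefficients)
  expect_equal(predict_scores(model, maps), ref, tolerance = 1e-12)
})

test_that("prediction metrics follow the MAE%% and R^2 definitions", {
  ev <- evaluate_predictions(c(10, 20), c(10, 20), 20)
  expect_equal(ev$mae_pct, 0)
  expect_equal(ev$accuracy, 1)
  expect_equal(ev$r2, 1)
  # worked example: measured (10, 20), predicted (12, 18), max 20
  ev2 <- evaluate_predictions(c(12, 18), c(10, 20), 20)
  expect_equal(ev2$mae, 2)
  expect_equal(ev2$mae_pct, 0.10)
  expect_equal(ev2$accuracy, 0.90)
  # random vectors match the scripted formula
  set.seed(7)
  p <- stats::rnorm(30); m <- stats::rnorm(30)
  ev3 <- evaluate_predictions(p, m, 5)
  expect_equal(ev3$mae_pct, sum(abs(m - p)) / 30 / 5, tolerance = 1e-12)
  expect_equal(ev3$r2, stats::cor(p, m)^2, tolerance = 1e-12)
  expect_equal(ev3$r2_signed, sign(stats::cor(p, m)) * stats::cor(p, m)^2)
  expect_warning(evaluate_predictions(p, rep(1, 30), 5), "variance")
  expect_error(evaluate_predictions(p, m[1:3], 5), "mismatch")
})

test_that("framework comparison is the standard paired t-test", {
  a <- c(0.2, 0.3, 0.4, 0.5)
  r0 <- compare_frameworks(a, a)
  expect_equal(r0$t, 0)
  expect_equal(r0$p, 1)
  # textbook paired differences 1, 2, 3, 4
  b <- a  # B
  a2 <- a + c(1, 2, 3, 4)
  r <- compare_frameworks(a2, b)
  dbar <- 2.5; sd_d <- stats::sd(c(1, 2, 3, 4))
  expect_equal(r$t, dbar / (sd_d / 2), tolerance = 1e-12)
  expect_equal(r$df, 3)
  expect_equal(r$p, 2 * stats::pt(-abs(r$t), df = 3), tolerance = 1e-12)
  # a planted mean shift across 86 simulated pairs is detected
  set.seed(8)
  base <- stats::runif(86, 0.1, 0.4)
  shifted <- base + stats::rnorm(86, mean = 0.05, sd = 0.05)
  expect_lt(compare_frameworks(shifted, base)$p, 0.05)
})
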