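#' Vectorize disconnectome maps over the brain mask
#'
#' Rows follow the input order; columns follow a fixed, documented voxel
#' order: the array-index (column-major) order of the brain-mask voxels.
#' [devectorize_map()] restores the in-mask volume exactly.
#'
#' @param disconnectomes list of `disconnectome` objects or 3-D arrays.
#' @param brain_mask binary 3-D array (nonempty).
#' @return Numeric matrix, n maps x n in-mask voxels.
#' @export
vectorize_maps <- function(disconnectomes, brain_mask) {
  sel <- which(brain_mask > 0)
  if (length(sel) == 0) stop("brain mask is empty")
  rows <- lapply(disconnectomes, function(d) {
    a <- if (inherits(d, "disconnectome")) d$data else d
    if (!identical(dim(a), dim(brain_mask)))
      stop("grid mismatch between map and brain mask")
    a[sel]
  })
  do.call(rbind, rows)
}

#' @rdname vectorize_maps
#' @param row one row of the vectorized matrix.
#' @export
devectorize_map <- function(row, brain_mask) {
  sel <- which(brain_mask > 0)
  if (length(row) != length(sel)) stop("row length does not match mask")
  out <- array(0, dim = dim(brain_mask))
  out[sel] <- row
  out
}

#' Fit a 2D UMAP morphospace from reference disconnectomes
#'
#' Embeds the reference disconnection profiles into two dimensions with
#' UMAP, and fixes the rasterization used for localisation-probability
#' images: a `resolution^2` pixel grid covering the reference bounding box
#' plus a margin, with an isotropic Gaussian smoothing sigma in pixels.
#' Seed-deterministic (single-threaded UMAP).
#'
#' @param mat reference matrix from [vectorize_maps()] (rows = maps).
#' @param n_neighbors,min_dist UMAP hyperparameters (defaults 15 and 0.1).
#' @param seed integer seed.
#' @param resolution raster edge in pixels (default 64).
#' @param sigma smoothing sigma in pixels (default 2).
#' @param margin_frac raster margin as a fraction of the embedding range.
#' @return A `morphospace` object: `ref_coords` (n x 2), `model` (the
#'   fitted reducer), `raster`, `sigma`, `seed`.
#' @export
fit_morphospace <- function(mat, n_neighbors = 15, min_dist = 0.1, seed = 1,
                            resolution = 64, sigma = 2, margin_frac = 0.25) {
  if (nrow(mat) < n_neighbors + 1)
    stop(sprintf("need at least n_neighbors + 1 = %d reference maps, got %d",
                 n_neighbors + 1, nrow(mat)))
  model <- with_seed(seed, {
    uwot::umap(mat, n_neighbors = n_neighbors, min_dist = min_dist,
               n_components = 2, ret_model = TRUE, n_threads = 1,
               n_sgd_threads = 0, verbose = FALSE)
  })
  coords <- model$embedding
  colnames(coords) <- c("UMAP1", "UMAP2")
  rng <- apply(coords, 2, range)
  span <- pmax(rng[2, ] - rng[1, ], 1e-6)
  lo <- rng[1, ] - margin_frac * span
  hi <- rng[2, ] + margin_frac * span
  raster <- list(nx = as.integer(resolution), ny = as.integer(resolution),
                 xmin = lo[1], xmax = hi[1], ymin = lo[2], ymax = hi[2])
  structure(list(ref_coords = coords, model = model, raster = raster,
                 sigma = sigma, seed = as.integer(seed)),
            class = "morphospace")
}

#' @export
print.morphospace <- function(x, ...) {
  cat(sprintf("<morphospace> %d reference maps, raster %dx%d, sigma %g px\n",
              nrow(x$ref_coords), x$raster$nx, x$raster$ny, x$sigma))
  invisible(x)
}

#' Embed new disconnectomes into a fitted morphospace
#'
#' Transforms without refitting; deterministic given the fitted state.
#'
#' @param morphospace a [fit_morphospace()] object.
#' @param mat matrix with the same column space as the reference matrix
#'   (may have zero rows).
#' @return m x 2 coordinate matrix.
#' @export
embed_new <- function(morphospace, mat) {
  if (is.null(dim(mat))) mat <- matrix(mat, nrow = 1)
  if (nrow(mat) == 0)
    return(matrix(numeric(0), 0, 2, dimnames = list(NULL, c("UMAP1", "UMAP2"))))
  if (ncol(mat) != ncol(morphospace$model$embedding) &&
      !is.null(morphospace$model$norig_col) &&
      ncol(mat) != morphospace$model$norig_col)
    stop("column count does not match the reference matrix")
  coords <- with_seed(morphospace$seed, {
    uwot::umap_transform(mat, morphospace$model, n_threads = 1,
                         n_sgd_threads = 0, verbose = FALSE)
  })
  colnames(coords) <- c("UMAP1", "UMAP2")
  coords
}

pixel_of <- function(coords, raster) {
  dx <- (raster$xmax - raster$xmin) / raster$nx
  dy <- (raster$ymax - raster$ymin) / raster$ny
  ix <- floor((coords[1] - raster$xmin) / dx)
  iy <- floor((coords[2] - raster$ymin) / dy)
  clamped <- FALSE
  if (ix < 0 || ix >= raster$nx) { ix <- min(max(ix, 0), raster$nx - 1); clamped <- TRUE }
  if (iy < 0 || iy >= raster$ny) { iy <- min(max(iy, 0), raster$ny - 1); clamped <- TRUE }
  list(ix = as.integer(ix), iy = as.integer(iy), clamped = clamped)
}

#' Localisation-probability image of one patient
#'
#' A delta at the pixel containing the patient's morphospace coordinate,
#' convolved with an isotropic Gaussian of the morphospace sigma and
#' renormalized to sum 1 (a probability image). Coordinates outside the
#' raster extent are clamped to the edge with a warning.
#'
#' @param coords numeric length-2 (UMAP1, UMAP2).
#' @param morphospace a [fit_morphospace()] object.
#' @return `nx x ny` matrix, non-negative, summing to 1.
#' @export
localisation_map <- function(coords, morphospace) {
  if (length(coords) != 2 || any(!is.finite(coords)))
    stop("coords must be two finite numbers")
  r <- morphospace$raster
  px <- pixel_of(coords, r)
  if (px$clamped)
    warning("coordinate outside the raster extent; clamped to the edge")
  gx <- stats::dnorm(seq_len(r$nx) - 1, mean = px$ix, sd = morphospace$sigma)
  gy <- stats::dnorm(seq_len(r$ny) - 1, mean = px$iy, sd = morphospace$sigma)
  img <- outer(gx, gy)
  img / sum(img)
}

#' Pixel-wise Pearson correlation of localisation with a score
#'
#' @param maps list of localisation images (one per patient, >= 3).
#' @param scores numeric vector of the patients' scores (non-constant).
#' @return A `correlation_map`: matrix of per-pixel Pearson R (NA where the
#'   patient values have zero variance), with `n_patients` attribute.
#' @export
pixelwise_correlation <- function(maps, scores) {
  n <- length(maps)
  if (n < 3) stop("need at least 3 patients")
  if (length(scores) != n) stop("scores length must match maps")
  if (stats::sd(scores) == 0) stop("scores are constant; correlation undefined")
  M <- vapply(maps, as.vector, numeric(length(maps[[1]])))   # pixels x patients
  mu <- rowMeans(M)
  Mc <- M - mu
  sc <- scores - mean(scores)
  denom_p <- sqrt(rowSums(Mc^2))
  denom_s <- sqrt(sum(sc^2))
  r <- as.vector(Mc %*% sc) / (denom_p * denom_s)
  r[denom_p == 0] <- NA_real_
  out <- matrix(r, nrow = nrow(maps[[1]]), ncol = ncol(maps[[1]]))
  structure(out, class = c("correlation_map", "matrix"),
            n_patients = n)
}

#' Extract score-associated territories from a correlation map
#'
#' Pixels with `|R|` strictly above the threshold (medium effect size 0.2
#' by default; both tails, since deficits may correlate negatively) are
#' grouped into 8-connected clusters; each cluster's informativeness is the
#' sum of `|R|` over its pixels, and the `top_k` most informative clusters
#' are kept. Ties break by cluster size, then by lowest pixel index. An
#' empty result is returned (not an error) when nothing survives.
#'
#' @param corrmap a [pixelwise_correlation()] result (or plain matrix).
#' @param threshold effect-size threshold in (0, 1), default 0.2.
#' @param top_k clusters to keep (default 3).
#' @param tails `"both"` (default) or `"positive"`.
#' @return A `territory_set`: list of clusters (`pixels` = integer indices
#'   into the raster, `informativeness`, `size`), possibly empty.
#' @export
extract_territories <- function(corrmap, threshold = 0.2, top_k = 3,
                                tails = c("both", "positive")) {
  tails <- match.arg(tails)
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  R <- unclass(corrmap)
  val <- if (tails == "both") abs(R) else R
  keep <- which(!is.na(val) & val > threshold)
  if (length(keep) == 0)
    return(structure(list(clusters = list(), threshold = threshold,
                          raster_dim = dim(R)), class = "territory_set"))
  nr <- nrow(R); nc <- ncol(R)
  pos <- arrayInd(keep, dim(R))
  key <- function(i, j) (j - 1L) * nr + i
  keep_set <- logical(nr * nc)
  keep_set[keep] <- TRUE
  edges <- integer(0)
  offs <- expand.grid(di = -1:1, dj = -1:1)
  offs <- offs[!(offs$di == 0 & offs$dj == 0), ]
  for (k in seq_len(nrow(offs))) {
    ni <- pos[, 1] + offs$di[k]; nj <- pos[, 2] + offs$dj[k]
    ok <- ni >= 1 & ni <= nr & nj >= 1 & nj <= nc
    ok[ok] <- keep_set[key(ni[ok], nj[ok])]
    if (any(ok))
      edges <- c(edges, rbind(keep[ok], key(ni[ok], nj[ok])))
  }
  g <- igraph::graph_from_edgelist(
    matrix(match(edges, keep), ncol = 2, byrow = TRUE), directed = FALSE)
  g <- igraph::add_vertices(g, max(0, length(keep) - igraph::vcount(g)))
  comp <- igraph::components(g)$membership
  clusters <- lapply(seq_len(max(comp)), function(ci) {
    px <- keep[comp == ci]
    list(pixels = sort(px),
         informativeness = sum(abs(R[px])),
         size = length(px))
  })
  info <- vapply(clusters, `[[`, numeric(1), "informativeness")
  size <- vapply(clusters, `[[`, numeric(1), "size")
  first <- vapply(clusters, function(cl) min(cl$pixels), numeric(1))
  ord <- order(-info, -size, first)
  clusters <- clusters[ord][seq_len(min(top_k, length(clusters)))]
  structure(list(clusters = clusters, threshold = threshold,
                 raster_dim = dim(R)), class = "territory_set")
}

#' @export
print.territory_set <- function(x, ...) {
  cat(sprintf("<territory_set> %d clusters (|R| > %g)\n",
              length(x$clusters), x$threshold))
  invisible(x)
}

territory_pixels <- function(territories) {
  unlist(lapply(territories$clusters, `[[`, "pixels"))
}

#' Fit the score-prediction model for one test
#'
#' Builds the patients x territory-pixel matrix of localisation values,
#' column-centres it, runs a PCA, keeps the first `min(n_components, rank)`
#' component scores as patient weights, and fits an ordinary least-squares
#' regression of the measured scores on those weights.
#'
#' @param maps list of localisation images (training patients).
#' @param territories a nonempty [extract_territories()] result.
#' @param scores numeric vector of measured scores.
#' @param n_components PCA components to keep (default 3).
#' @param test_name label stored in the model.
#' @return A `score_model`: `territories`, `center`, `rotation`,
#'   `coefficients` (intercept first), `n_components`, `fitted`.
#' @export
fit_score_model <- function(maps, territories, scores, n_components = 3,
                            test_name = "test") {
  if (length(territories$clusters) == 0) stop("territory set is empty")
  n <- length(maps)
  if (n < 3) stop("need at least 3 patients to fit a score model")
  px <- territory_pixels(territories)
  X <- t(vapply(maps, function(m) as.vector(m)[px], numeric(length(px))))
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)
  pc <- stats::prcomp(Xc, center = FALSE)
  tol <- max(pc$sdev) * 1e-8
  rank <- sum(pc$sdev > tol)
  if (rank < 1) stop("territory localisation values have rank 0")
  k <- min(n_components, rank, n - 2)
  if (k < n_components)
    warning(sprintf("components truncated from %d to rank %d", n_components, k))
  W <- pc$x[, seq_len(k), drop = FALSE]
  fit <- stats::lm.fit(cbind(1, W), scores)
  structure(list(test_name = test_name, territories = territories,
                 center = ctr, rotation = pc$rotation[, seq_len(k), drop = FALSE],
                 coefficients = fit$coefficients, n_components = k,
                 fitted = as.vector(cbind(1, W) %*% fit$coefficients)),
            class = "score_model")
}

#' Predict scores from localisation maps
#'
#' @param model a [fit_score_model()] object.
#' @param maps list of localisation images on the model's raster.
#' @return Numeric vector of predicted scores.
#' @export
predict_scores <- function(model, maps) {
  px <- territory_pixels(model$territories)
  rd <- model$territories$raster_dim
  for (m in maps)
    if (!identical(dim(m), rd)) stop("raster mismatch with the fitted model")
  X <- t(vapply(maps, function(m) as.vector(m)[px], numeric(length(px))))
  W <- sweep(X, 2, model$center) %*% model$rotation
  as.vector(cbind(1, W) %*% model$coefficients)
}

#' Evaluate predicted against measured scores
#'
#' `MAE%` is the mean absolute error divided by the maximum attainable
#' score; accuracy is `1 - MAE%`; `r2` is the squared Pearson correlation of
#' predicted versus measured (`NaN` with a flag if the measured scores have
#' zero variance). `r2_signed` additionally carries the sign of the
#' correlation (`sign(r) * r^2`), the statistic whose chance level is zero;
#' it is what permutation-null summaries should average.
#'
#' @param predicted,measured numeric vectors of equal length.
#' @param max_score positive scalar, the maximum attainable score.
#' @return List: `mae`, `mae_pct`, `accuracy`, `r2`, `r2_signed`, `n`.
#' @export
evaluate_predictions <- function(predicted, measured, max_score) {
  if (length(predicted) != length(measured)) stop("length mismatch")
  if (max_score <= 0) stop("max_score must be > 0")
  mae <- mean(abs(measured - predicted))
  mae_pct <- mae / max_score
  if (stats::sd(measured) == 0 || stats::sd(predicted) == 0) {
    warning("zero variance; R^2 undefined")
    r <- NaN
  } else {
    r <- stats::cor(predicted, measured)
  }
  list(mae = mae, mae_pct = mae_pct, accuracy = 1 - mae_pct,
       r2 = r^2, r2_signed = sign(r) * r^2, n = length(measured))
}

#' Paired comparison of two prediction frameworks
#'
#' Standard two-tailed paired t-test on per-test R-squared lists.
#'
#' @param r2_a,r2_b numeric vectors of equal length (>= 3), paired by test.
#' @return List: `t`, `df`, `p`, `mean_diff` (A - B).
#' @export
compare_frameworks <- function(r2_a, r2_b) {
  if (length(r2_a) != length(r2_b)) stop("length mismatch")
  if (length(r2_a) < 3) stop("need at least 3 paired values")
  d <- r2_a - r2_b
  if (stats::sd(d) == 0) {
    if (all(d == 0)) return(list(t = 0, df = length(d) - 1, p = 1, mean_diff = 0))
    stop("zero-variance nonzero differences; t undefined")
  }
  tt <- stats::t.test(r2_a, r2_b, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean_diff = mean(d))
}
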