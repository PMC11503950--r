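#' @useDynLib deepdisco, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Run code under a temporarily seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Voxel-centre coordinate grids (centre of voxel i is i + 0.5).
voxel_centres <- function(shape) {
  list(x = seq_len(shape[1]) - 0.5,
       y = seq_len(shape[2]) - 0.5,
       z = seq_len(shape[3]) - 0.5)
}

#' Generate an ellipsoidal brain mask
#'
#' The phantom "brain" is a filled ellipsoid inscribed in the grid with a
#' safety margin: centre at `(shape - 1)/2 + 0.5` (the grid midpoint in
#' continuous voxel coordinates) and semi-axes `shape/2 - margin`. A voxel
#' belongs to the mask when its centre satisfies the ellipsoid inequality.
#' Deterministic.
#'
#' @param grid a [grid_spec()].
#' @param margin shrink per axis in voxels (must be `< min(shape)/2`).
#' @return A binary 3-D array (0/1) of the grid's shape.
#' @examples
#' g <- grid_spec(c(16, 16, 16))
#' m <- make_brain_mask(g, margin = 1)
#' sum(m)
#' @export
make_brain_mask <- function(grid, margin = 1) {
  shape <- grid$shape
  semi <- shape / 2 - margin
  if (any(semi <= 0))
    stop("margin too large: mask would be empty (need margin < min(shape)/2)")
  centre <- shape / 2
  cc <- voxel_centres(shape)
  qx <- ((cc$x - centre[1]) / semi[1])^2
  qy <- ((cc$y - centre[2]) / semi[2])^2
  qz <- ((cc$z - centre[3]) / semi[3])^2
  q <- outer(outer(qx, qy, `+`), qz, `+`)
  mask <- array(as.numeric(q <= 1), dim = shape)
  if (sum(mask) == 0) stop("margin too large: mask is empty")
  mask
}

# Quadratic form of the brain ellipsoid at continuous points (n x 3); < 1 is
# inside. Used to keep spines inside the mask with a safety factor.
ellipsoid_q <- function(pts, shape, margin) {
  semi <- shape / 2 - margin
  centre <- shape / 2
  ((pts[, 1] - centre[1]) / semi[1])^2 +
    ((pts[, 2] - centre[2]) / semi[2])^2 +
    ((pts[, 3] - centre[3]) / semi[3])^2
}

#' Generate synthetic white-matter bundles
#'
#' Builds `n_bundles` bundle spines inside the brain mask, alternating two
#' morphologies: long spines running end-to-end across the ellipsoid (core
#' long pathways) and short peripheral arcs hugging the surface (the
#' phantom's stand-in for short U-shaped association fibres). All control
#' points are verified to lie inside the mask; placement retries a bounded
#' number of times.
#'
#' @param grid a [grid_spec()].
#' @param n_bundles number of bundles (>= 1).
#' @param radius_range length-2 numeric, tube radius bounds in voxels.
#' @param seed integer seed; the result is a pure function of the arguments.
#' @param margin brain-mask margin used for containment checks (must match
#'   the mask the bundles will live in).
#' @param max_tries placement retries per bundle before failing.
#' @return A list of `bundle` objects (`spine` control-point matrix,
#'   `radius`, `id`, `kind` = "long"/"short").
#' @export
make_bundles <- function(grid, n_bundles, radius_range = c(0.8, 1.6), seed = 1,
                         margin = 1, max_tries = 200) {
  if (n_bundles < 1) stop("n_bundles must be >= 1")
  shape <- grid$shape
  semi <- shape / 2 - margin
  centre <- shape / 2
  with_seed(seed, {
    bundles <- vector("list", n_bundles)
    for (b in seq_len(n_bundles)) {
      kind <- if (b %% 2 == 1) "long" else "short"
      radius <- stats::runif(1, radius_range[1], radius_range[2])
      placed <- FALSE
      for (try in seq_len(max_tries)) {
        spine <- if (kind == "long") {
          axis <- ((b - 1) %/% 2) %% 3 + 1
          n_ctrl <- 7L
          t <- seq(-0.82, 0.82, length.out = n_ctrl)
          perp <- setdiff(1:3, axis)
          amp <- stats::runif(2, -0.35, 0.35)
          phase <- stats::runif(2, 0, 2 * pi)
          pts <- matrix(0, n_ctrl, 3)
          pts[, axis] <- centre[axis] + t * semi[axis]
          for (k in 1:2) {
            off <- stats::runif(1, -0.3, 0.3)
            pts[, perp[k]] <- centre[perp[k]] +
              semi[perp[k]] * (off + amp[k] * sin(pi * (t + 1) / 2 + phase[k]))
          }
          pts
        } else {
          # short arc: quadratic Bezier between two nearby sub-surface points,
          # bulging outward
          u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
          v <- stats::rnorm(3); v <- v - sum(v * u) * u
          v <- v / sqrt(sum(v * v))
          ang <- stats::runif(1, 0.35, 0.6)       # radians of angular span
          p1 <- cos(-ang / 2) * u + sin(-ang / 2) * v
          p2 <- cos(ang / 2) * u + sin(ang / 2) * v
          r_in <- 0.68; r_out <- 0.86
          P1 <- centre + r_in * semi * p1
          P2 <- centre + r_in * semi * p2
          Pc <- centre + r_out * semi * u
          tt <- seq(0, 1, length.out = 7L)
          pts <- outer((1 - tt)^2, P1) + outer(2 * tt * (1 - tt), Pc) +
            outer(tt^2, P2)
          pts
        }
        if (all(ellipsoid_q(spine, shape, margin) <= 0.93)) {
          bundles[[b]] <- structure(
            list(spine = spine, radius = radius,
                 id = sprintf("bundle%02d", b), kind = kind),
            class = "bundle")
          placed <- TRUE
          break
        }
      }
      if (!placed)
        stop(sprintf("could not place bundle %d inside the brain mask after %d tries",
                     b, max_tries))
    }
    bundles
  })
}

# Resample a polyline to equal arc-length steps of at most `step` voxels.
# Returns the points and, for jittering, the normalized arc position of each.
resample_polyline <- function(pts, step) {
  seg <- sqrt(rowSums((pts[-1, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE])^2))
  cum <- c(0, cumsum(seg))
  total <- cum[length(cum)]
  if (total == 0) {
    return(list(points = pts[c(1, 1), , drop = FALSE], s = c(0, 0), total = 0))
  }
  n_out <- max(2L, ceiling(total / step) + 1L)
  s <- seq(0, total, length.out = n_out)
  out <- cbind(stats::approx(cum, pts[, 1], xout = s)$y,
               stats::approx(cum, pts[, 2], xout = s)$y,
               stats::approx(cum, pts[, 3], xout = s)$y)
  list(points = out, s = s, total = total)
}

# Smooth unit-variance offset curve: iid N(0,1) values at the spine knots,
# linearly interpolated along arc length, then rescaled so that every
# interpolated point keeps marginal variance 1 (interpolation with weight w
# has variance w^2 + (1-w)^2 < 1, which the rescale undoes).
smooth_unit_offsets <- function(knot_s, sample_s) {
  k <- length(knot_s)
  vals <- stats::rnorm(k)
  idx <- findInterval(sample_s, knot_s, rightmost.closed = TRUE, all.inside = TRUE)
  w <- (sample_s - knot_s[idx]) / pmax(knot_s[idx + 1] - knot_s[idx], 1e-12)
  w <- pmin(pmax(w, 0), 1)
  raw <- (1 - w) * vals[idx] + w * vals[idx + 1]
  raw / sqrt(w^2 + (1 - w)^2)
}

#' Sample one subject's tractogram from a set of bundles
#'
#' Each streamline is the bundle spine resampled at a fixed arc-length step
#' (default 0.5 voxel) plus a smooth Gaussian offset whose per-point,
#' per-coordinate marginal standard deviation is exactly `jitter_sd`. With
#' `jitter_sd = 0` every streamline equals its resampled spine. Points are
#' clamped to the grid interior so traversal is always defined.
#'
#' @param bundles list of bundles from [make_bundles()].
#' @param grid a [grid_spec()].
#' @param per_bundle streamlines per bundle (>= 1).
#' @param jitter_sd per-coordinate offset standard deviation, voxels (>= 0).
#' @param seed integer seed.
#' @param subject_id label stored in the tractogram.
#' @param step resampling step in voxels (<= 0.5).
#' @return A `tractogram` object with `per_bundle * length(bundles)`
#'   streamlines and per-streamline bundle labels.
#' @export
sample_subject_tractogram <- function(bundles, grid, per_bundle = 10,
                                      jitter_sd = 0.5, seed = 1,
                                      subject_id = "subj", step = 0.5) {
  if (per_bundle < 1) stop("per_bundle must be >= 1")
  if (jitter_sd < 0) stop("jitter_sd must be >= 0")
  if (step > 0.5) stop("resampling step must be <= 0.5 voxel")
  shape <- grid$shape
  with_seed(seed, {
    streamlines <- list()
    labels <- character(0)
    for (bd in bundles) {
      rs <- resample_polyline(bd$spine, step)
      knot_s <- c(0, cumsum(sqrt(rowSums(
        (bd$spine[-1, , drop = FALSE] - bd$spine[-nrow(bd$spine), , drop = FALSE])^2))))
      for (k in seq_len(per_bundle)) {
        pts <- rs$points
        if (jitter_sd > 0) {
          off <- vapply(1:3, function(j) smooth_unit_offsets(knot_s, rs$s),
                        numeric(nrow(pts)))
          pts <- pts + jitter_sd * off
        }
        # clamp into the open grid interior
        for (j in 1:3) pts[, j] <- pmin(pmax(pts[, j], 1e-4), shape[j] - 1e-4)
        streamlines[[length(streamlines) + 1L]] <- pts
        labels[length(labels) + 1L] <- bd$id
      }
    }
    new_tractogram(subject_id, streamlines, labels)
  })
}

#' Generate a random focal lesion inside the brain mask
#'
#' An ellipsoidal blob: centre drawn uniformly over brain-mask voxels,
#' per-axis semi-axes uniform in `radius_range`, rasterized over voxel
#' centres and intersected with the brain mask. Resamples internally (up to
#' `max_tries`) if the intersection comes out empty.
#'
#' @param brain_mask binary 3-D array from [make_brain_mask()].
#' @param grid a [grid_spec()].
#' @param radius_range length-2 numeric, semi-axis bounds in voxels.
#' @param seed integer seed.
#' @param max_tries resampling attempts before failing.
#' @return A `lesion_mask` object.
#' @export
make_lesion <- function(brain_mask, grid, radius_range = c(2, 5), seed = 1,
                        max_tries = 50) {
  check_volume(brain_mask, grid, "brain mask")
  if (any(radius_range <= 0) || radius_range[2] < radius_range[1])
    stop("radius_range must be increasing and positive")
  shape <- grid$shape
  inside <- which(brain_mask > 0)
  if (length(inside) == 0) stop("brain mask is empty")
  cc <- voxel_centres(shape)
  with_seed(seed, {
    for (try in seq_len(max_tries)) {
      ctr_idx <- inside[sample.int(length(inside), 1)]
      ijk <- arrayInd(ctr_idx, shape)
      centre <- as.numeric(ijk) - 0.5       # centre of the chosen voxel
      semi <- stats::runif(3, radius_range[1], radius_range[2])
      qx <- ((cc$x - centre[1]) / semi[1])^2
      qy <- ((cc$y - centre[2]) / semi[2])^2
      qz <- ((cc$z - centre[3]) / semi[3])^2
      q <- outer(outer(qx, qy, `+`), qz, `+`)
      blob <- (q <= 1) & (brain_mask > 0)
      if (any(blob))
        return(lesion_mask(grid, array(as.numeric(blob), dim = shape)))
    }
    stop("could not generate a nonempty lesion after ", max_tries, " tries")
  })
}

#' Cohort ground truth for planted behavioural scores
#'
#' @param bundle_weights tests x bundles matrix of effect sizes (a score is
#'   `sum_b w_b * severity_b` plus noise); rows may be all-zero for explicit
#'   null tests.
#' @param noise_sd additive Gaussian score noise (>= 0).
#' @param seed integer seed used when scores are drawn.
#' @return A `cohort_truth` object.
#' @export
cohort_truth <- function(bundle_weights, noise_sd = 0, seed = 1) {
  bundle_weights <- as.matrix(bundle_weights)
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (is.null(rownames(bundle_weights)))
    rownames(bundle_weights) <- sprintf("test%02d", seq_len(nrow(bundle_weights)))
  structure(list(bundle_weights = bundle_weights, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "cohort_truth")
}

#' Per-bundle disconnection severity of a lesion
#'
#' For each bundle, the fraction of that bundle's streamlines — pooled over
#' all subjects — whose traversed voxels intersect the lesion.
#'
#' @param lesion a `lesion_mask`.
#' @param tractograms list of `tractogram` objects.
#' @param grid a [grid_spec()].
#' @param cache optional traversal cache from [streamline_voxel_cache()].
#' @return Named numeric vector over bundle ids, values in \[0, 1\].
#' @export
bundle_severity <- function(lesion, tractograms, grid, cache = NULL) {
  if (is.null(cache)) cache <- streamline_voxel_cache(tractograms, grid)
  les <- as.logical(lesion$data > 0)
  sev_num <- integer(0); sev_den <- integer(0)
  for (t in seq_along(cache$trav)) {
    labs <- cache$bundle_of[[t]]
    hits <- vapply(cache$trav[[t]], function(v) any(les[v]), logical(1))
    for (b in unique(labs)) {
      sel <- labs == b
      sev_num[b] <- (if (is.na(sev_num[b])) 0L else sev_num[b]) + sum(hits[sel])
      sev_den[b] <- (if (is.na(sev_den[b])) 0L else sev_den[b]) + sum(sel)
    }
  }
  out <- sev_num / sev_den
  out[sort(names(out))]
}

#' Generate planted behavioural scores for a lesion cohort
#'
#' Per patient and bundle, the disconnection severity `s_b` is the fraction
#' of the bundle's streamlines (pooled over subjects) intersecting the
#' lesion; the score for test `t` is `sum_b W[t, b] * s_b` plus
#' `N(0, noise_sd)` noise. `max_score` per test is the observed cohort
#' maximum rounded up (and at least 1).
#'
#' @param lesions list of `lesion_mask` objects (>= 1 patient).
#' @param tractograms list of `tractogram` objects.
#' @param grid a [grid_spec()].
#' @param truth a [cohort_truth()]; its weight columns must match the number
#'   of bundles present in the tractograms.
#' @param cache optional traversal cache ([streamline_voxel_cache()]).
#' @return A `score_table`: `patients`, `tests`, `measured` (patients x
#'   tests), `max_score`, and the underlying `severity` matrix (patients x
#'   bundles).
#' @export
make_scores <- function(lesions, tractograms, grid, truth, cache = NULL) {
  if (length(lesions) < 1) stop("need at least one patient lesion")
  if (is.null(cache)) cache <- streamline_voxel_cache(tractograms, grid)
  bundle_ids <- sort(unique(unlist(lapply(cache$bundle_of, unique))))
  W <- truth$bundle_weights
  if (ncol(W) != length(bundle_ids))
    stop(sprintf("weight dimension %d does not match %d bundles",
                 ncol(W), length(bundle_ids)))
  colnames(W) <- bundle_ids
  sev <- t(vapply(lesions, function(l)
    bundle_severity(l, tractograms, grid, cache = cache),
    numeric(length(bundle_ids))))
  signal <- sev %*% t(W)                      # patients x tests
  measured <- with_seed(truth$seed, {
    signal + matrix(stats::rnorm(length(signal), 0, truth$noise_sd),
                    nrow = nrow(signal))
  })
  patients <- sprintf("patient%03d", seq_along(lesions))
  dimnames(measured) <- list(patients, rownames(W))
  max_score <- pmax(ceiling(apply(measured, 2, max)), 1)
  structure(list(patients = patients, tests = rownames(W),
                 measured = measured, max_score = max_score,
                 severity = sev),
            class = "score_table")
}

#' @export
print.score_table <- function(x, ...) {
  cat(sprintf("<score_table> %d patients x %d tests\n",
              length(x$patients), length(x$tests)))
  invisible(x)
}

#' Write / read a score table as CSV plus a JSON sidecar for max_score
#'
#' @param scores a `score_table`.
#' @param path CSV output path (`patient_id` column then one column per
#'   test); `<path>.meta.json` stores `max_score`.
#' @return The path, invisibly.
#' @export
write_scores <- function(scores, path) {
  df <- data.frame(patient_id = scores$patients,
                   scores$measured, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(as.list(scores$max_score), paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_scores
#' @export
read_scores <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  measured <- as.matrix(df[, -1, drop = FALSE])
  rownames(measured) <- df$patient_id
  meta <- paste0(path, ".meta.json")
  max_score <- if (file.exists(meta)) {
    unlist(jsonlite::read_json(meta, simplifyVector = TRUE))
  } else {
    pmax(ceiling(apply(measured, 2, max)), 1)
  }
  structure(list(patients = df$patient_id, tests = colnames(measured),
                 measured = measured, max_score = max_score[colnames(measured)],
                 severity = NULL),
            class = "score_table")
}
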