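#' Voxels traversed by a streamline
#'
#' The polyline is densely resampled at a fixed arc-length step (default 0.1
#' voxel) and each sample point is assigned to the voxel `floor(p)`; the
#' original vertices are always included. This is an approximation to the
#' exact 3-D supercover of the polyline whose error shrinks with the step.
#'
#' @param streamline n x 3 matrix of continuous voxel coordinates (n >= 2),
#'   all points inside the grid bounds.
#' @param grid a [grid_spec()].
#' @param step resampling step in voxels.
#' @return Sorted integer vector of 1-based linear voxel indices
#'   (column-major) of the traversed voxels.
#' @export
voxels_traversed <- function(streamline, grid, step = 0.1) {
  if (!is.matrix(streamline) || ncol(streamline) != 3 || nrow(streamline) < 2)
    stop("streamline must be an n x 3 matrix with n >= 2")
  if (!all(is.finite(streamline))) stop("streamline contains non-finite points")
  shape <- grid$shape
  for (j in 1:3) {
    bad <- streamline[, j] < 0 | streamline[, j] >= shape[j]
    if (any(bad)) {
      p <- streamline[which(bad)[1], ]
      stop(sprintf("streamline point (%.3f, %.3f, %.3f) outside grid %s",
                   p[1], p[2], p[3], paste(shape, collapse = "x")))
    }
  }
  pts <- resample_polyline(streamline, step)$points
  pts <- rbind(pts, streamline)
  ijk <- floor(pts)
  for (j in 1:3) ijk[, j] <- pmin(ijk[, j], shape[j] - 1)  # boundary p == shape never occurs (checked)
  idx <- 1 + ijk[, 1] + shape[1] * (ijk[, 2] + shape[2] * ijk[, 3])
  sort(unique(as.integer(idx)))
}

#' Precompute traversal sets for a cohort of tractograms
#'
#' Computing a disconnectome for many lesions against the same normative
#' tractograms repeats every streamline traversal; this cache computes each
#' streamline's voxel set once.
#'
#' @param tractograms list of `tractogram` objects.
#' @param grid a [grid_spec()].
#' @param step traversal resampling step in voxels.
#' @return A `traversal_cache`: per subject, the list of traversal index
#'   vectors and the bundle labels.
#' @export
streamline_voxel_cache <- function(tractograms, grid, step = 0.1) {
  trav <- lapply(tractograms, function(t)
    lapply(t$streamlines, voxels_traversed, grid = grid, step = step))
  structure(list(trav = trav,
                 bundle_of = lapply(tractograms, `[[`, "bundle_of"),
                 grid = grid),
            class = "traversal_cache")
}

#' Does a streamline pass through the lesion?
#'
#' @param streamline n x 3 matrix in voxel coordinates.
#' @param lesion a `lesion_mask`.
#' @param step traversal step.
#' @return `TRUE` iff the streamline's traversed voxels intersect the lesion.
#' @export
streamline_hits_lesion <- function(streamline, lesion, step = 0.1) {
  idx <- voxels_traversed(streamline, lesion$grid, step = step)
  any(lesion$data[idx] > 0)
}

#' Per-subject visitation map for a lesion
#'
#' The union of traversed voxels over exactly those of the subject's
#' streamlines that pass through the lesion.
#'
#' @param tractogram a `tractogram`.
#' @param lesion a `lesion_mask` on the same grid.
#' @param grid a [grid_spec()] (must match the lesion's).
#' @param step traversal step.
#' @return Binary 3-D array.
#' @export
subject_visitation <- function(tractogram, lesion, grid = lesion$grid, step = 0.1) {
  stopifnot_same_grid(grid, lesion$grid, "tractogram grid and lesion")
  trav <- lapply(tractogram$streamlines, voxels_traversed, grid = grid, step = step)
  visitation_from_cache(trav, lesion)
}

visitation_from_cache <- function(trav, lesion) {
  les <- lesion$data > 0
  out <- array(0, dim = lesion$grid$shape)
  hit <- vapply(trav, function(v) any(les[v]), logical(1))
  if (any(hit)) out[unique(unlist(trav[hit]))] <- 1
  out
}

#' Compute a conventional disconnectome
#'
#' For each normative subject, mark the voxels visited by that subject's
#' lesion-crossing streamlines; the disconnectome value at a voxel is the
#' proportion of subjects whose visitation covers it — a map from 0 to 1
#' quantized to multiples of 1/N. Values outside the brain mask (when given)
#' are zeroed.
#'
#' @param lesion a `lesion_mask`.
#' @param tractograms list of `tractogram` objects (>= 1), or `NULL` when a
#'   `cache` is supplied.
#' @param brain_mask optional binary 3-D array.
#' @param cache optional [streamline_voxel_cache()] (overrides `tractograms`).
#' @param step traversal step.
#' @return A `disconnectome` object.
#' @export
compute_disconnectome <- function(lesion, tractograms = NULL, brain_mask = NULL,
                                  cache = NULL, step = 0.1) {
  if (is.null(cache)) {
    if (is.null(tractograms) || length(tractograms) == 0)
      stop("need at least one tractogram (or a traversal cache)")
    cache <- streamline_voxel_cache(tractograms, lesion$grid, step = step)
  } else {
    stopifnot_same_grid(cache$grid, lesion$grid, "cache and lesion")
  }
  n <- length(cache$trav)
  if (n == 0) stop("need at least one tractogram")
  acc <- array(0, dim = lesion$grid$shape)
  for (t in seq_len(n)) acc <- acc + visitation_from_cache(cache$trav[[t]], lesion)
  d <- acc / n
  if (!is.null(brain_mask)) {
    check_volume(brain_mask, lesion$grid, "brain mask")
    d <- d * (brain_mask > 0)
  }
  new_disconnectome(lesion$grid, d, n_subjects = n)
}

#' Voxelwise average of disconnectome maps
#'
#' @param disconnectomes list of `disconnectome` objects or 3-D arrays with a
#'   shared shape (>= 1).
#' @return A 3-D array, the arithmetic mean; used as the fixed second input
#'   channel of the network.
#' @export
average_template <- function(disconnectomes) {
  if (length(disconnectomes) < 1) stop("need at least one map")
  as_arr <- function(d) if (inherits(d, "disconnectome")) d$data else d
  a0 <- as_arr(disconnectomes[[1]])
  acc <- array(0, dim = dim(a0))
  for (d in disconnectomes) {
    a <- as_arr(d)
    if (!identical(dim(a), dim(a0))) stop("shape mismatch across maps")
    acc <- acc + a
  }
  acc / length(disconnectomes)
}

#' Binarize a disconnectome
#'
#' A voxel is disconnected when its value strictly exceeds the threshold.
#' The default threshold 0.0001 turns any quantized value k/N (k >= 1,
#' N <= 10000 subjects) into 1 while treating exact-threshold values as
#' background.
#'
#' @param d a `disconnectome` or 3-D array.
#' @param threshold scalar >= 0 (default 0.0001, strict inequality).
#' @return Binary 3-D array.
#' @export
binarize_disconnectome <- function(d, threshold = 1e-4) {
  if (threshold < 0) stop("threshold must be >= 0")
  a <- if (inherits(d, "disconnectome")) d$data else d
  array(as.numeric(a > threshold), dim = dim(a))
}

#' Frequency map of disconnected voxels
#'
#' @param binary_maps list of binary 3-D arrays with a shared shape (>= 1).
#' @return A `frequency_map`: `data` is the voxelwise mean (values in
#'   `{0, 1/n, ..., 1}`), `n` the number of maps aggregated.
#' @export
frequency_map <- function(binary_maps) {
  if (length(binary_maps) < 1) stop("need at least one binary map")
  a0 <- binary_maps[[1]]
  acc <- array(0, dim = dim(a0))
  for (m in binary_maps) {
    if (!identical(dim(m), dim(a0))) stop("shape mismatch across maps")
    acc <- acc + m
  }
  structure(list(data = acc / length(binary_maps), n = length(binary_maps)),
            class = "frequency_map")
}
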