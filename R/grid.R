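#' Define the common sampling grid
#'
#' All volumes in a study share one grid: a voxel lattice of given shape with
#' isotropic spacing. Geometry throughout the package uses continuous,
#' 0-based voxel coordinates; a point `p` occupies voxel `floor(p)`, and the
#' voxel with (0-based) index `i` has its centre at `i + 0.5`. The affine is
#' the diagonal voxel-to-world scaling `diag(voxel_size)`.
#'
#' @param shape integer vector of length 3, voxels per axis (each >= 8).
#' @param voxel_size voxel edge length in mm (isotropic, > 0).
#' @return An object of class `grid_spec` with fields `shape`, `voxel_size`
#'   and `affine` (4 x 4 matrix).
#' @examples
#' g <- grid_spec(c(16, 16, 16), voxel_size = 2)
#' g$shape
#' @export
grid_spec <- function(shape, voxel_size = 1) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(!is.finite(shape)))
    stop("shape must be 3 integers")
  if (any(shape < 8L)) stop("every grid dimension must be >= 8 voxels")
  if (!is.numeric(voxel_size) || length(voxel_size) != 1L || voxel_size <= 0)
    stop("voxel_size must be a single positive number")
  affine <- diag(c(rep(voxel_size, 3), 1))
  structure(list(shape = shape, voxel_size = voxel_size, affine = affine),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d x %d voxels @ %g mm\n",
              x$shape[1], x$shape[2], x$shape[3], x$voxel_size))
  invisible(x)
}

same_grid <- function(a, b) {
  identical(a$shape, b$shape) && isTRUE(all.equal(a$voxel_size, b$voxel_size))
}

stopifnot_same_grid <- function(a, b, what = "volumes") {
  if (!same_grid(a, b))
    stop(sprintf("grid mismatch between %s: %s vs %s", what,
                 paste(a$shape, collapse = "x"), paste(b$shape, collapse = "x")))
  invisible(TRUE)
}

check_volume <- function(data, grid, what = "volume") {
  d <- dim(data)
  if (is.null(d) || length(d) != 3L)
    stop(sprintf("%s must be a 3-D array", what))
  if (!identical(as.integer(d), grid$shape))
    stop(sprintf("%s shape %s does not match grid %s", what,
                 paste(d, collapse = "x"), paste(grid$shape, collapse = "x")))
  invisible(TRUE)
}

#' Construct a lesion mask object
#'
#' @param grid a [grid_spec()].
#' @param data binary 3-D array (0/1) on `grid`.
#' @return An object of class `lesion_mask`.
#' @export
lesion_mask <- function(grid, data) {
  check_volume(data, grid, "lesion")
  if (!all(data %in% c(0, 1))) stop("lesion data must be binary (0/1)")
  structure(list(grid = grid, data = array(as.numeric(data), dim = grid$shape)),
            class = "lesion_mask")
}

#' @export
print.lesion_mask <- function(x, ...) {
  cat(sprintf("<lesion_mask> %s, %d lesioned voxels\n",
              paste(x$grid$shape, collapse = "x"), sum(x$data > 0)))
  invisible(x)
}

new_disconnectome <- function(grid, data, n_subjects = NA_integer_) {
  check_volume(data, grid, "disconnectome")
  structure(list(grid = grid, data = data, n_subjects = n_subjects),
            class = "disconnectome")
}

#' @export
print.disconnectome <- function(x, ...) {
  cat(sprintf("<disconnectome> %s, range [%.3f, %.3f], %s subjects\n",
              paste(x$grid$shape, collapse = "x"),
              min(x$data), max(x$data),
              ifelse(is.na(x$n_subjects), "?", x$n_subjects)))
  invisible(x)
}
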