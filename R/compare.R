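#' Cohort-level pairwise R-squared between deep and conventional maps
#'
#' Per pair, the squared Pearson correlation over in-mask voxels (see
#' [goodness_of_fit()]); the cohort value is the mean over pairs.
#' Degenerate zero-variance pairs are flagged `NaN` and excluded from the
#' mean with a warning (silently scoring them 0 would bias the headline
#' mean), and their count is reported.
#'
#' @param deep,conv lists of `disconnectome` objects or 3-D arrays, equal
#'   length and paired order.
#' @param brain_mask binary 3-D array.
#' @return List: `per_pair` (numeric vector, `NaN` for degenerate pairs),
#'   `mean`, `n_excluded`.
#' @export
cohort_pairwise_r2 <- function(deep, conv, brain_mask) {
  if (length(deep) != length(conv)) stop("deep/conv length mismatch")
  per <- vapply(seq_along(deep), function(i)
    suppressWarnings(goodness_of_fit(deep[[i]], conv[[i]], brain_mask)),
    numeric(1))
  bad <- !is.finite(per)
  if (any(bad))
    warning(sprintf("%d degenerate pair(s) excluded from the mean", sum(bad)))
  list(per_pair = per, mean = mean(per[!bad]), n_excluded = sum(bad))
}

#' Signed contrast of two frequency maps
#'
#' Voxelwise `freq_conv - freq_deep`: positive values mark structure that
#' the conventional maps flag as disconnected more often than the deep
#' surrogate (under-captured structure, e.g. short peripheral fibres),
#' negative values the reverse. Antisymmetric under argument swap.
#'
#' @param freq_conv,freq_deep `frequency_map` objects or 3-D arrays on a
#'   shared grid.
#' @return 3-D array of signed differences.
#' @export
frequency_contrast <- function(freq_conv, freq_deep) {
  a <- if (inherits(freq_conv, "frequency_map")) freq_conv$data else freq_conv
  b <- if (inherits(freq_deep, "frequency_map")) freq_deep$data else freq_deep
  if (!identical(dim(a), dim(b))) stop("grid mismatch between frequency maps")
  a - b
}

#' Average Euclidean distance profile of a 2D embedding
#'
#' Entry `i` is the mean Euclidean distance from point `i` to every other
#' point; permuting the points permutes the profile identically.
#'
#' @param coords n x 2 coordinate matrix (n >= 2).
#' @return A `distance_profile`: numeric vector of length n.
#' @export
distance_profile <- function(coords) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (n < 2) stop("need at least 2 points")
  D <- as.matrix(stats::dist(coords))
  prof <- rowSums(D) / (n - 1)
  structure(as.numeric(prof), class = "distance_profile", n = n)
}

#' Bland-Altman summary of two paired profiles
#'
#' Differences `A - B`; mean, standard deviation (n-1 denominator),
#' agreement limits `mean +/- 2 SD`, and the 95% confidence interval of the
#' mean difference (`mean +/- t_{0.975, n-1} * SD / sqrt(n)`).
#'
#' @param profile_a,profile_b numeric vectors of equal length (>= 2), paired.
#' @return A `bland_altman` list: `differences`, `mean`, `sd`, `limits`
#'   (lower, upper), `ci` (lower, upper), `n`.
#' @export
bland_altman <- function(profile_a, profile_b) {
  a <- as.numeric(profile_a); b <- as.numeric(profile_b)
  if (length(a) != length(b)) stop("profile length mismatch")
  if (length(a) < 2) stop("need at least 2 paired values")
  d <- a - b
  m <- mean(d)
  s <- stats::sd(d)
  n <- length(d)
  tq <- stats::qt(0.975, df = n - 1)
  structure(list(differences = d, mean = m, sd = s,
                 limits = c(lower = m - 2 * s, upper = m + 2 * s),
                 ci = c(lower = m - tq * s / sqrt(n),
                        upper = m + tq * s / sqrt(n)),
                 n = n),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("<bland_altman> mean %.4f, SD %.4f, limits [%.4f, %.4f], n = %d\n",
              x$mean, x$sd, x$limits[1], x$limits[2], x$n))
  invisible(x)
}
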