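# Shared fixture builders. Everything is generated in code, seeded, and
# small enough to run in seconds.

tiny_grid <- function(n = 12, vs = 1) grid_spec(rep(n, 3), vs)

# A small phantom world: grid, mask, bundles, subject tractograms, cache.
tiny_world <- function(n = 12, n_bundles = 3, n_subjects = 3, per_bundle = 4,
                       jitter_sd = 0.3, seed = 11) {
  g <- tiny_grid(n)
  mask <- make_brain_mask(g, 1)
  bundles <- make_bundles(g, n_bundles, seed = seed)
  tracts <- lapply(seq_len(n_subjects), function(i)
    sample_subject_tractogram(bundles, g, per_bundle = per_bundle,
                              jitter_sd = jitter_sd, seed = seed + 100 + i,
                              subject_id = sprintf("s%02d", i)))
  list(grid = g, mask = mask, bundles = bundles, tracts = tracts,
       cache = streamline_voxel_cache(tracts, g))
}

# Independent brute-force disconnectome: enumerates (subject, streamline,
# sample point) triples explicitly and does its own set arithmetic. It
# realizes the same traversal definition — voxels containing any point of
# the polyline resampled at equal arc-length steps of at most 0.1 voxel,
# plus the original vertices — but shares no code with the package
# (explicit per-point loops, own arc-length interpolation).
brute_force_traversal <- function(s, step = 0.1) {
  seglen <- numeric(nrow(s) - 1)
  for (k in seq_len(nrow(s) - 1))
    seglen[k] <- sqrt(sum((s[k + 1, ] - s[k, ])^2))
  total <- sum(seglen)
  if (total == 0) return(unique(floor(s)))
  cum <- c(0, cumsum(seglen))
  n_out <- max(2, ceiling(total / step) + 1)
  svals <- seq(0, total, length.out = n_out)
  pts <- matrix(0, n_out, 3)
  for (i in seq_len(n_out)) {
    k <- findInterval(svals[i], cum, rightmost.closed = TRUE, all.inside = TRUE)
    lam <- (svals[i] - cum[k]) / max(seglen[k], 1e-300)
    pts[i, ] <- s[k, ] + lam * (s[k + 1, ] - s[k, ])
  }
  unique(floor(rbind(pts, s)))
}

brute_force_disconnectome <- function(lesion, tractograms, step = 0.1) {
  shape <- lesion$grid$shape
  acc <- array(0, dim = shape)
  for (tr in tractograms) {
    visited <- array(FALSE, dim = shape)
    for (s in tr$streamlines) {
      vox <- brute_force_traversal(s, step)
      hit <- FALSE
      for (r in seq_len(nrow(vox)))
        if (lesion$data[vox[r, 1] + 1, vox[r, 2] + 1, vox[r, 3] + 1] > 0) {
          hit <- TRUE
          break
        }
      if (hit)
        for (r in seq_len(nrow(vox)))
          visited[vox[r, 1] + 1, vox[r, 2] + 1, vox[r, 3] + 1] <- TRUE
    }
    acc <- acc + visited
  }
  acc / length(tractograms)
}

# A lesion covering one given voxel (1-based index triple).
point_lesion <- function(grid, ijk) {
  a <- array(0, dim = grid$shape)
  a[ijk[1], ijk[2], ijk[3]] <- 1
  lesion_mask(grid, a)
}

# Hand-built straight streamline through given voxel-centre coordinates.
seg <- function(from, to) rbind(from, to)
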