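test_that("voxels_traversed handles axis-aligned, degenerate and diagonal segments", {
  g <- tiny_grid(12)
  # axis-parallel segment crosses exactly the voxels along x
  idx <- voxels_traversed(seg(c(1.5, 1.5, 1.5), c(4.5, 1.5, 1.5)), g)
  expected <- sapply(1:4, function(x) 1 + x + 12 * (1 + 12 * 1))
  expect_identical(idx, sort(as.integer(expected)))
  # repeated single point occupies one voxel
  idx2 <- voxels_traversed(rbind(c(2.2, 2.2, 2.2), c(2.2, 2.2, 2.2)), g)
  expect_identical(idx2, as.integer(1 + 2 + 12 * (2 + 12 * 2)))
  # diagonal agrees with a 10x finer sampling
  sl <- seg(c(0.5, 0.5, 0.5), c(3.5, 3.5, 3.5))
  expect_identical(voxels_traversed(sl, g, step = 0.1),
                   voxels_traversed(sl, g, step = 0.01))
  # out-of-bounds points are named in the error
  expect_error(voxels_traversed(seg(c(-1, 2, 2), c(3, 2, 2)), g), "outside grid")
})

test_that("streamline/lesion intersection follows traversal sets", {
  g <- tiny_grid(12)
  sl <- seg(c(1.5, 5.5, 5.5), c(9.5, 5.5, 5.5))
  expect_true(streamline_hits_lesion(sl, point_lesion(g, c(6, 6, 6))))
  expect_false(streamline_hits_lesion(sl, point_lesion(g, c(6, 8, 6))))
  empty <- lesion_mask(g, array(0, dim = g$shape))
  expect_false(streamline_hits_lesion(sl, empty))
  # random streamlines vs random lesion match an explicit set intersection
  set.seed(4)
  les_arr <- array(as.numeric(stats::runif(12^3) < 0.03), dim = g$shape)
  les <- lesion_mask(g, les_arr)
  for (k in 1:10) {
    sl <- matrix(stats::runif(9, 1, 11), ncol = 3)
    hit_ref <- length(intersect(voxels_traversed(sl, g), which(les_arr > 0))) > 0
    expect_identical(streamline_hits_lesion(sl, les), hit_ref)
  }
})

test_that("subject visitation is the union over hitting streamlines", {
  g <- tiny_grid(12)
  s1 <- seg(c(1.5, 3.5, 3.5), c(8.5, 3.5, 3.5))   # hits
  s2 <- seg(c(1.5, 3.5, 7.5), c(8.5, 3.5, 7.5))   # misses
  s3 <- seg(c(5.5, 1.5, 3.5), c(5.5, 8.5, 3.5))   # hits (crosses s1 path)
  tr <- deepdisco:::new_tractogram("s", list(s1, s2, s3), c("a", "a", "b"))
  les <- point_lesion(g, c(6, 4, 4))
  vis <- subject_visitation(tr, les)
  manual <- array(0, dim = g$shape)
  manual[union(voxels_traversed(s1, g), voxels_traversed(s3, g))] <- 1
  expect_identical(vis, manual)
  # no streamline hits -> all zero
  vis0 <- subject_visitation(tr, point_lesion(g, c(11, 11, 11)))
  expect_true(all(vis0 == 0))
  # single hitting streamline equals its traversal set
  tr1 <- deepdisco:::new_tractogram("s", list(s1), "a")
  vis1 <- subject_visitation(tr1, les)
  expect_identical(which(vis1 == 1), as.integer(voxels_traversed(s1, g)))
})

test_that("disconnectome equals subject-count fractions and brute force", {
  w <- tiny_world(12, n_bundles = 3, n_subjects = 4, per_bundle = 3, seed = 7)
  # empty lesion -> zero map
  d0 <- compute_disconnectome(lesion_mask(w$grid, array(0, dim = w$grid$shape)),
                              w$tracts)
  expect_true(all(d0$data == 0))
  # N = 1 subject equals that subject's visitation
  les <- make_lesion(w$mask, w$grid, c(2, 3), seed = 5)
  d1 <- compute_disconnectome(les, w$tracts[1])
  expect_identical(d1$data, subject_visitation(w$tracts[[1]], les))
  # full cohort matches the independent brute-force enumeration exactly
  d <- compute_disconnectome(les, w$tracts)
  bf <- brute_force_disconnectome(les, w$tracts)
  expect_identical(d$data, bf)
  # quantization: every value times N is an integer in [0, N]
  k <- d$data * length(w$tracts)
  expect_true(all(abs(k - round(k)) < 1e-9))
  expect_true(all(k >= 0 & k <= length(w$tracts)))
  # a voxel visited by 3 of 4 subjects scores 0.75
  counts <- Reduce(`+`, lapply(w$tracts, function(t)
    subject_visitation(t, les)))
  if (any(counts == 3)) {
    v <- which(counts == 3)[1]
    expect_equal(d$data[v], 0.75)
  }
  # masking zeroes everything outside the brain mask
  dm <- compute_disconnectome(les, w$tracts, brain_mask = w$mask)
  expect_true(all(dm$data[w$mask == 0] == 0))
})

test_that("disconnectome is monotone in the lesion", {
  w <- tiny_world(12, n_bundles = 3, n_subjects = 3, per_bundle = 4, seed = 3)
  set.seed(21)
  for (k in 1:20) {
    a <- make_lesion(w$mask, w$grid, c(1, 3), seed = 300 + k)
    grow <- make_lesion(w$mask, w$grid, c(2, 4), seed = 400 + k)
    b_arr <- pmax(a$data, grow$data)              # A is a subset of B
    b <- lesion_mask(w$grid, b_arr)
    da <- compute_disconnectome(a, cache = w$cache)
    db <- compute_disconnectome(b, cache = w$cache)
    expect_true(all(db$data - da$data >= -1e-12))
  }
})

test_that("average template is the voxelwise mean", {
  w <- tiny_world(10, n_subjects = 2, seed = 9)
  les <- make_lesion(w$mask, w$grid, c(2, 3), seed = 2)
  d <- compute_disconnectome(les, w$tracts)
  expect_identical(average_template(list(d, d, d)), d$data)
  half <- average_template(list(array(0, dim = w$grid$shape),
                                array(1, dim = w$grid$shape)))
  expect_true(all(half == 0.5))
  # five random maps match an explicit voxel loop
  set.seed(8)
  maps <- lapply(1:5, function(i) array(stats::runif(1000), dim = c(10, 10, 10)))
  avg <- average_template(maps)
  ref <- array(0, dim = c(10, 10, 10))
  for (v in seq_len(1000)) ref[v] <- mean(sapply(maps, `[[`, v))
  expect_equal(avg, ref, tolerance = 1e-12)
  expect_error(average_template(list(maps[[1]], array(0, dim = c(9, 10, 10)))),
               "shape")
})

test_that("binarization uses a strict threshold and preserves oracle support", {
  a <- array(c(0, 1e-4, 1.0001e-4, 0.5), dim = c(4, 1, 1) + c(0, 0, 0))
  dim(a) <- c(4, 1, 1)
  b <- binarize_disconnectome(a)
  expect_equal(as.numeric(b), c(0, 0, 1, 1))    # exact threshold -> background
  # oracle quantization k/N for N <= 10000 means support is preserved
  w <- tiny_world(10, n_subjects = 4, seed = 13)
  les <- make_lesion(w$mask, w$grid, c(2, 3), seed = 3)
  d <- compute_disconnectome(les, w$tracts)
  expect_identical(binarize_disconnectome(d), array(as.numeric(d$data > 0),
                                                    dim = w$grid$shape))
  # random map agrees with an elementwise reference loop
  set.seed(5)
  r <- array(stats::runif(125, 0, 2e-4), dim = c(5, 5, 5))
  bb <- binarize_disconnectome(r, threshold = 1e-4)
  ref <- array(0, dim = dim(r))
  for (v in seq_along(r)) ref[v] <- as.numeric(r[v] > 1e-4)
  expect_identical(bb, ref)
})

test_that("frequency maps average binary masks with n recorded", {
  m1 <- array(as.numeric(stats::runif(27) > 0.5), dim = c(3, 3, 3))
  f1 <- frequency_map(list(m1))
  expect_identical(f1$data, m1)
  expect_identical(f1$n, 1L)
  f2 <- frequency_map(list(m1, 1 - m1))
  expect_true(all(f2$data == 0.5))
  set.seed(6)
  maps <- lapply(1:6, function(i) array(as.numeric(stats::runif(27) > 0.5),
                                        dim = c(3, 3, 3)))
  f6 <- frequency_map(maps)
  ref <- array(0, dim = c(3, 3, 3))
  for (v in seq_len(27)) ref[v] <- mean(sapply(maps, `[[`, v))
  expect_equal(f6$data, ref, tolerance = 1e-12)
  expect_true(all(abs(f6$data * 6 - round(f6$data * 6)) < 1e-9))
})
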