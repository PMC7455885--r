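test_that("volume is exactly count times voxel volume", {
  m <- array(FALSE, c(10, 10, 10))
  m[1:5, 1:5, 1:2] <- TRUE  # 50 voxels
  expect_equal(compute_volume(region_mask(m, "ON_L", c(2, 2, 2))), 400)
  m1 <- array(FALSE, c(5, 5, 5)); m1[3, 3, 3] <- TRUE
  expect_equal(compute_volume(region_mask(m1, "ON_L", c(1, 1, 1))), 1)
  expect_error(compute_volume(region_mask(array(FALSE, c(4, 4, 4)),
                                          "ON_L", c(1, 1, 1))),
               "empty-region")
})

test_that("square phantom perimeter equals the enumerated boundary walk", {
  # 5x5 solid square: 16 boundary voxels, every 8-connected step is an
  # axis step of length 1 -> 16 mm
  sl <- matrix(FALSE, 9, 9); sl[3:7, 3:7] <- TRUE
  expect_equal(compute_perimeter(sl, c(1, 1)), 16)
  # single voxel: degenerate one-point loop
  s1 <- matrix(FALSE, 5, 5); s1[3, 3] <- TRUE
  expect_equal(compute_perimeter(s1, c(1, 1)), 0)
  # anisotropic in-plane spacing scales the axis steps
  expect_equal(compute_perimeter(sl, c(2, 1)), 2 * 8 + 8)
})

test_that("disk perimeter matches an independent angular-order boundary walk", {
  for (r in c(6, 10)) {
    sl <- make_disk_slice(r)
    expect_equal(compute_perimeter(sl, c(1, 1)),
                 oracle_perimeter_convex(sl), tolerance = 1e-10)
  }
})

test_that("perimeter sums over disconnected in-plane components", {
  sl <- matrix(FALSE, 12, 12)
  sl[2:4, 2:4] <- TRUE   # 3x3 square: 8 boundary voxels, perimeter 8
  sl[8:10, 8:10] <- TRUE
  expect_equal(compute_perimeter(sl, c(1, 1)), 16)
})

test_that("morphology is invariant under axis-aligned translation", {
  set.seed(9)
  base <- make_cylinder_mask(3, 10)
  shifted <- array(FALSE, dim(base$mask) + c(3L, 2L, 1L))
  idx <- which(base$mask, arr.ind = TRUE)
  shifted[idx + matrix(rep(c(3L, 2L, 1L), each = nrow(idx)), ncol = 3)] <- TRUE
  rm2 <- region_mask(shifted, "ON_L", c(1, 1, 1))
  f1 <- morphology_features(base)
  f2 <- morphology_features(rm2)
  expect_equal(f1, f2)
})

test_that("boundary count scales linearly and area quadratically on upsampling", {
  # same physical disk (radius 6 mm) at 1 mm and at 0.5 mm spacing
  coarse <- make_disk_slice(6)
  fine <- make_disk_slice(12, size = 2 * nrow(coarse))
  per_c <- compute_perimeter(coarse, c(1, 1))
  per_f <- compute_perimeter(fine, c(0.5, 0.5))
  expect_lt(abs(per_f - per_c) / per_c, 0.05)
  area_c <- sum(coarse) * 1
  area_f <- sum(fine) * 0.25
  expect_lt(abs(area_f - area_c) / area_c, 0.05)
})

test_that("cylinder thickness recovers the phantom radius", {
  th4 <- compute_thickness(make_cylinder_mask(4, 20))
  expect_lt(abs(mean(th4) - 4), 0.5)  # within one voxel
  # 1-voxel-wide line: all samples at the degenerate centre
  m <- array(FALSE, c(7, 7, 12)); m[4, 4, 2:11] <- TRUE
  thin <- compute_thickness(region_mask(m, "ON_L", c(1, 1, 1)))
  expect_true(all(thin <= sqrt(2) / 2 + 1e-12))
  # widening the tube strictly increases mean thickness
  th3 <- compute_thickness(make_cylinder_mask(3, 20))
  th5 <- compute_thickness(make_cylinder_mask(5, 20))
  expect_lt(mean(th3), mean(th4))
  expect_lt(mean(th4), mean(th5))
})

test_that("tortuosity index is area over perimeter with a guarded zero", {
  expect_equal(compute_tortuosity_index(100, 40), 2.5)
  expect_error(compute_tortuosity_index(10, 0), "undefined-ratio")
  # equal areas: the boundary-convoluted shape has the smaller index
  compact <- matrix(FALSE, 9, 9); compact[3:7, 3:7] <- TRUE     # 25 voxels
  line <- matrix(FALSE, 3, 29); line[2, 3:27] <- TRUE           # 25 voxels
  ic <- compute_tortuosity_index(sum(compact), compute_perimeter(compact, c(1, 1)))
  il <- compute_tortuosity_index(sum(line), compute_perimeter(line, c(1, 1)))
  expect_lt(il, ic)
})

test_that("morphology summary stats are ordered and non-negative", {
  f <- morphology_features(make_cylinder_mask(3, 12))
  expect_true(all(f >= 0))
  for (op in c("perimeter", "thickness", "tortuosity")) {
    expect_lte(f[paste0("ON_L_", op, "_min")], f[paste0("ON_L_", op, "_mean")])
    expect_lte(f[paste0("ON_L_", op, "_mean")], f[paste0("ON_L_", op, "_max")])
  }
})

test_that("ROI-logic filtering equals the brute-force predicate", {
  set.seed(21)
  g <- c(20L, 20L, 20L); sp <- c(1, 1, 1)
  roi_a <- opgpredict:::make_box_mask(g, sp, c(3, 10, 10), c(2, 3, 3), "ROI_A")
  roi_b <- opgpredict:::make_box_mask(g, sp, c(16, 10, 10), c(2, 3, 3), "ROI_B")
  roi_c <- opgpredict:::make_box_mask(g, sp, c(10, 15, 10), c(2, 2, 2), "ROI_C")
  lines <- lapply(seq_len(100), function(i) {
    n <- sample(2:6, 1)
    matrix(runif(n * 3, 0, 19), n, 3)
  })
  sl <- streamline_set(lines)
  kept <- filter_streamlines(sl, roi_a, roi_b, roi_c)
  oracle_keep <- vapply(lines, function(l)
    oracle_line_hits_mask(l, roi_a) && oracle_line_hits_mask(l, roi_b) &&
      !oracle_line_hits_mask(l, roi_c), logical(1))
  expect_identical(kept$lines, lines[oracle_keep])
  # explicit cases: through A and B kept; additionally through C removed
  thr <- streamline_set(list(rbind(c(3, 10, 10), c(16, 10, 10)),
                             rbind(c(3, 10, 10), c(10, 15, 10), c(16, 10, 10))))
  expect_equal(filter_streamlines(thr, roi_a, roi_b, roi_c)$count, 1L)
  bad <- region_mask(array(FALSE, c(10, 10, 10)), "ROI_C", sp)
  expect_error(filter_streamlines(thr, roi_a, roi_b, bad), "geometry error")
})

test_that("streamline voxelization marks exactly the traversed voxels", {
  g <- c(16L, 16L, 16L); sp <- c(1, 1, 1)
  # axis-aligned line across voxel centres 3..12 (world 2..11)
  l <- rbind(c(2, 5, 5), c(11, 5, 5))
  m <- streamlines_to_mask(streamline_set(list(l)), g, sp)
  expect_equal(sum(m$mask), 10L)
  expect_true(all(m$mask[3:12, 6, 6]))
  # union property
  l2 <- rbind(c(5, 2, 8), c(5, 13, 8))
  m1 <- streamlines_to_mask(streamline_set(list(l)), g, sp)$mask
  m2 <- streamlines_to_mask(streamline_set(list(l2)), g, sp)$mask
  m12 <- streamlines_to_mask(streamline_set(list(l, l2)), g, sp)$mask
  expect_identical(m12, m1 | m2)
  expect_error(streamlines_to_mask(streamline_set(list()), g, sp),
               "empty-region")
})

test_that("dense bundles rasterize like the brute-force oracle", {
  set.seed(31)
  g <- c(20L, 20L, 20L); sp <- c(1, 1, 1)
  lines <- lapply(seq_len(50), function(i) {
    y <- runif(1, 3, 16); z <- runif(1, 3, 16)
    rbind(c(2, y, z), c(17, y + runif(1, -1, 1), z + runif(1, -1, 1)))
  })
  sl <- streamline_set(lines)
  m <- streamlines_to_mask(sl, g, sp)
  expect_identical(m$mask, oracle_rasterize(sl, g, sp))
})
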