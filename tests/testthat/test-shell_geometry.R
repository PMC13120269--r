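test_that("isotropic resampling: constant, identity, and linear ramp oracle", {
  const <- image_volume(array(1.52, c(8, 8, 4)), spacing = c(1, 1, 3))
  r <- resample_isotropic(const, target_mm = 1)
  expect_equal(unique(as.vector(r$volume$data)), 1.52)
  expect_equal(r$volume$spacing, c(1, 1, 1))

  set.seed(3)
  v <- image_volume(array(rnorm(7^3), c(7, 7, 7)))
  ri <- resample_isotropic(v, target_mm = 1)
  expect_equal(ri$volume$data, v$data, tolerance = 1e-12)

  # f(z) = z (mm): trilinear interpolation must reproduce the ramp at the
  # new voxel-center coordinates exactly
  ramp <- image_volume(array(rep(seq(0, 12, by = 3), each = 25), c(5, 5, 5)),
                       spacing = c(1, 1, 3))
  rr <- resample_isotropic(ramp, target_mm = 1)
  zc <- (seq_len(dim(rr$volume$data)[3]) - 1) * 1
  expect_lt(max(abs(sweep(rr$volume$data, 3, zc))), 1e-6)
  # physical extent preserved within one voxel
  expect_lte(abs((dim(rr$volume$data)[3] - 1) * 1 - 12), 1)

  expect_error(resample_isotropic(const, target_mm = -1), "parameter")
})

test_that("resampling interpolates masks nearest-neighbor and re-binarizes", {
  v <- image_volume(array(0, c(6, 6, 4)), spacing = c(1, 1, 2))
  m <- array(0, c(6, 6, 4)); m[3:4, 3:4, 2:3] <- 1
  mk <- binary_mask(m, spacing = c(1, 1, 2))
  r <- resample_isotropic(v, masks = list(mk), target_mm = 1)
  expect_true(all(r$masks[[1]]$data %in% c(TRUE, FALSE)))
  expect_gt(sum(r$masks[[1]]$data), 0)
})

test_that("one-voxel 6-connected erosion matches the neighborhood oracle", {
  cube <- array(0, c(5, 5, 5)); cube[2:4, 2:4, 2:4] <- 1
  er <- erode_one_voxel(binary_mask(cube))
  expect_equal(sum(er$data), 1)
  expect_true(er$data[3, 3, 3])

  single <- array(0, c(5, 5, 5)); single[3, 3, 3] <- 1
  expect_warning(fb <- erode_one_voxel(binary_mask(single)), "falling back")
  expect_true(attr(fb, "erosion_fallback"))
  expect_equal(sum(fb$data), 1)

  sph <- make_sphere_mask(6)
  er2 <- erode_one_voxel(sph)
  expect_identical(er2$data, brute_force_erode(sph$data))
})

test_that("distance field equals the exhaustive nearest-tumor-voxel oracle", {
  # unit step: face-adjacent voxel at 1 mm
  t1 <- array(0, c(7, 7, 7)); t1[4, 4, 4] <- 1
  f1 <- boundary_distance_field(binary_mask(t1))$data
  expect_equal(f1[5, 4, 4], 1)
  expect_equal(f1[4, 4, 4], 0)
  # 3-4-5 triangle
  expect_equal(f1[7, 4, 4], 3)
  t2 <- array(0, c(11, 11, 3)); t2[6, 6, 2] <- 1
  f2 <- boundary_distance_field(binary_mask(t2))$data
  expect_equal(f2[9, 10, 2], 5)

  # random blobs, anisotropic spacing, vs O(N*M) brute force
  for (seed in 1:3) {
    sp <- list(c(1, 1, 1), c(1.2, 0.8, 2), c(0.7, 1.3, 1))[[seed]]
    bl <- make_blob_mask(c(20, 17, 13), spacing = sp, seed = seed)
    expect_equal(boundary_distance_field(bl)$data, brute_force_edt(bl),
                 tolerance = 1e-12)
  }
  expect_error(boundary_distance_field(
    binary_mask(array(0, c(3, 3, 3)), role = "exclusion")), "empty-mask")
})

test_that("build_shells matches exhaustive distance classification on blobs", {
  for (seed in 1:2) {
    bl <- make_blob_mask(c(24, 20, 16), seed = seed + 10)
    ss <- suppressWarnings(build_shells(bl))
    bf <- brute_force_edt(bl)
    for (k in 1:3) {
      inner <- ss$specs$inner_mm[k]; outer <- ss$specs$outer_mm[k]
      expect_identical(ss$shells[[k]]$data,
                       bf > inner & bf <= outer & !bl$data)
    }
  }
})

test_that("shells partition, respect exclusions, and flag clipping", {
  sph <- make_sphere_mask(5, dim = c(41, 41, 41))
  ss <- build_shells(sph)
  # pairwise disjoint: tumor VOI and shells never overlap
  tot <- ss$tumor_voi$data + Reduce(`+`, lapply(ss$shells, `[[`, "data"))
  expect_lte(max(tot), 1)
  # un-eroded tumor and shells tile their union without double assignment
  tot2 <- sph$data + Reduce(`+`, lapply(ss$shells, `[[`, "data"))
  expect_lte(max(tot2), 1)

  # exclusion beyond 5 mm empties shell 3
  bf <- boundary_distance_field(sph)$data
  excl <- binary_mask(array(as.numeric(bf > 5), dim(bf)), role = "exclusion")
  ss2 <- build_shells(sph, exclusion = excl)
  expect_true(ss2$empty[3])
  expect_equal(sum(ss2$shells[[3]]$data), 0)
  expect_false(ss2$empty[1])

  # tumor 3 mm from the border clips the 5-10 mm shell
  near <- make_sphere_mask(5, dim = c(21, 41, 41), center = c(8, 20, 20))
  ss3 <- build_shells(near)
  expect_true(ss3$clipped[3])
  centered <- make_sphere_mask(5, dim = c(41, 41, 41))
  expect_false(any(build_shells(centered)$clipped))

  expect_error(build_shells(sph, data.frame(inner_mm = c(0, 1),
                                            outer_mm = c(2, 3))),
               "overlap")
})

test_that("digital-sphere shell volumes track the analytic closed form", {
  R <- 10
  sph <- make_sphere_mask(R, dim = c(61, 61, 61))
  ss <- build_shells(sph)
  rel <- sapply(1:3, function(k) {
    analytic <- 4 * pi / 3 * ((R + ss$specs$outer_mm[k])^3 -
                                (R + ss$specs$inner_mm[k])^3)
    (sum(ss$shells[[k]]$data) - analytic) / analytic
  })
  # thick bands agree closely with the continuous spherical-shell volume
  expect_lt(abs(rel[2]), 0.07)
  expect_lt(abs(rel[3]), 0.07)
  # the thinnest band systematically under-fills on a jagged digital
  # surface (voxel-center distances overestimate surface distance); the
  # bias is bounded and negative
  expect_lt(rel[1], 0)
  expect_lt(abs(rel[1]), 0.20)
})

test_that("enlarging a shell's outer bound never removes voxels", {
  bl <- make_blob_mask(c(22, 18, 15), seed = 99)
  base <- suppressWarnings(build_shells(bl, data.frame(inner_mm = 2, outer_mm = 5)))
  wider <- suppressWarnings(build_shells(bl, data.frame(inner_mm = 2, outer_mm = 7)))
  expect_true(all(wider$shells[[1]]$data[base$shells[[1]]$data]))
})

test_that("contralateral mirror preserves cardinality and is an involution", {
  vol <- image_volume(array(0, c(40, 30, 20)))
  m <- array(0, c(40, 30, 20)); m[28:32, 10:14, 8:12] <- 1
  tv <- binary_mask(m)
  ref <- mirror_reference_voi(tv, vol)
  expect_equal(sum(ref$data), sum(tv$data))
  expect_equal(range(which(apply(ref$data, 3, any))),
               range(which(apply(tv$data, 3, any))))
  # centered 20 voxels right of the x mid-plane -> 20 voxels left
  cx_t <- mean(which(apply(tv$data, 1, any)))
  cx_r <- mean(which(apply(ref$data, 1, any)))
  expect_equal(cx_t - (40 + 1) / 2, (40 + 1) / 2 - cx_r)
  # involution
  back <- mirror_reference_voi(ref, vol)
  expect_identical(back$data, tv$data)

  # tumor crossing the midline cannot be mirrored
  m2 <- array(0, c(40, 30, 20)); m2[18:23, 10:14, 8:12] <- 1
  expect_error(mirror_reference_voi(binary_mask(m2), vol), "geometry")
})
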