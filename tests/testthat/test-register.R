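# register module: correlation metric, coarse search, rigid refinement,
# pose application and 2D affine registration.

test_that("correlation coefficient matches its closed form", {
  A <- rand_image(64, seed = 5)
  expect_equal(correlation_coefficient(A, A), 1, tolerance = 1e-12)
  expect_equal(correlation_coefficient(A, 7 - A), -1, tolerance = 1e-12)
  # hand example: T = (1,2,3,4), R = (1,2,3,5)
  # sum of deviation products = 6.5; sums of squares = 5 and 8.75
  expect_equal(correlation_coefficient(matrix(1:4, 2), matrix(c(1, 2, 3, 5), 2)),
               6.5 / sqrt(5 * 8.75), tolerance = 1e-12)
  expect_error(correlation_coefficient(matrix(1, 3, 3), A[1:3, 1:3]),
               "constant")
  expect_error(correlation_coefficient(A, A[1:10, 1:10]), "equal shapes")
})

test_that("C is symmetric and invariant to positive affine rescaling", {
  for (seed in 1:5) {
    A <- rand_image(24, seed)
    B <- rand_image(24, seed + 100)
    expect_equal(correlation_coefficient(A, B),
                 correlation_coefficient(B, A), tolerance = 1e-12)
    expect_equal(correlation_coefficient(3.2 * A + 11, B),
                 correlation_coefficient(A, 0.5 * B - 2), tolerance = 1e-12)
    expect_gte(correlation_coefficient(A, B), -1)
    expect_lte(correlation_coefficient(A, B), 1)
  }
})

test_that("coarse search recovers a known axis-aligned offset", {
  scaf <- small_scaffold()
  vmask <- vol3d(as_plain(scaf$mask), 20, labels = TRUE)
  sp <- 20
  z0 <- 8                                        # voxels from centre
  pose0 <- rigid_pose(c(0, 0, 0), c(0, 0, z0 * sp), sp)
  sec <- extract_section(vmask, pose0, thickness_um = sp, interp = "nearest")
  grid <- search_grid(inplane_deg = seq(0, 355, 5), tilt_deg = c(-5, 0, 5),
                      offset_stride = 1)
  cand <- coarse_search(sec, vmask, grid, thickness_um = sp)
  # even z-dimension: grid offsets sit on half-integer voxel planes
  expect_lte(abs(cand$offset_vox[1] - z0), 0.5)
  expect_equal(cand$inplane_deg[1] %% 360, 0)
  expect_equal(cand$C[1], 1, tolerance = 1e-9)   # identical slab
  # ranking is insensitive to grid order
  grid_rev <- search_grid(inplane_deg = rev(seq(0, 355, 5)),
                          tilt_deg = c(5, 0, -5), offset_stride = 1)
  cand_rev <- coarse_search(sec, vmask, grid_rev, thickness_um = sp)
  expect_equal(cand_rev$offset_vox[1], cand$offset_vox[1])
  expect_equal(cand_rev$C[1], cand$C[1], tolerance = 1e-12)
  expect_error(coarse_search(section2d(matrix(0L, 8, 8), 20, labels = TRUE),
                             vmask), "empty section mask")
})

test_that("refine_rigid: thickness rule, fixed point, monotone trace", {
  scaf <- small_scaffold()
  vmask <- vol3d(as_plain(scaf$mask), 20, labels = TRUE)
  sp <- 20
  truth <- rigid_pose(c(10, 4, -3), c(30, -25, 90), 60)
  sec <- extract_section(vmask, truth, thickness_um = 60, interp = "nearest",
                         reduce = "max")
  # thickness of one voxel allows only a 2D (3 DOF) transformation;
  # above 5 voxels the full 6 DOF are used
  f1 <- refine_rigid(sec, vmask, truth, thickness_um = sp, max_iter = 5)
  expect_equal(f1$dof_used, 3L)
  f6 <- refine_rigid(sec, vmask, truth, thickness_um = 6 * sp, max_iter = 5)
  expect_equal(f6$dof_used, 6L)
  f3 <- refine_rigid(sec, vmask, truth, thickness_um = 3 * sp, max_iter = 5)
  expect_equal(f3$dof_used, 3L)
  # starting at the truth, the pose stays put
  fit <- refine_rigid(sec, vmask, truth, thickness_um = 60)
  pd <- pose_difference(fit$pose, truth)
  expect_lt(pd$translation_um, 0.5 * sp)
  expect_lt(pd$rotation_deg, 0.5)
  expect_gte(fit$final_C, 0.95)   # off-grid pose: interpolation mismatch
  expect_true(all(diff(fit$trace) >= 0))
  expect_equal(fit$final_C, tail(fit$trace, 1))
  # a voxel-aligned pose resamples exactly, so C is essentially perfect
  truth0 <- rigid_pose(c(0, 0, 0), c(0, 0, 90), 60)
  sec0 <- extract_section(vmask, truth0, thickness_um = 60,
                          interp = "nearest", reduce = "max")
  fit0 <- refine_rigid(sec0, vmask, truth0, thickness_um = 60)
  expect_gte(fit0$final_C, 0.99)
})

test_that("refine_rigid recovers a perturbed pose on noiseless masks", {
  scaf <- small_scaffold()
  vmask <- vol3d(as_plain(scaf$mask), 20, labels = TRUE)
  sp <- 20
  truth <- rigid_pose(c(25, 6, -4), c(40, 10, 60), 60)
  sec <- extract_section(vmask, truth, thickness_um = 60, interp = "nearest",
                         reduce = "max")
  init <- rigid_pose(c(27, 4, -2), c(40 + sp, 10 - sp, 60 + sp), 60)
  fit <- refine_rigid(sec, vmask, init, thickness_um = 60, dof = 6)
  pd <- pose_difference(fit$pose, truth)
  expect_lt(pd$translation_um / sp, 0.5)
  expect_lt(pd$rotation_deg, 0.5)
  expect_gte(fit$final_C, 0.97)
})

test_that("apply_pose returns the registered correspondence", {
  ph <- small_phantom()
  ct <- quiet_ct(ph$labels)
  d <- dim(ct); sp <- spacing_um(ct)
  k <- 30L
  pose <- rigid_pose(c(0, 0, 0), c(0, 0, (k - 1 - (d[3] - 1) / 2) * sp))
  expect_equal(as.vector(apply_pose(ct, pose, thickness_um = sp)),
               as.vector(unclass(ct)[, , k]), tolerance = 1e-9)
  # a registered pose reproduces the section titanium mask
  scafmask <- ph$truth$scaffold_mask
  truth <- rigid_pose(c(12, 5, -2), c(10, -20, 40), 60)
  sec <- extract_section(scafmask, truth, thickness_um = 60,
                         interp = "nearest", reduce = "max")
  slab <- apply_pose(scafmask, truth, thickness_um = 60, interp = "nearest",
                     reduce = "max")
  expect_gte(dice(unclass(slab) > 0, unclass(sec) > 0), 0.97)
})

test_that("register_affine2d recovers imposed affine transforms", {
  # ring mask, transformed analytically
  n <- 160
  x <- seq_len(n) - (n + 1) / 2
  r2 <- outer(x^2, x^2, "+")
  ring <- section2d(((r2 >= 30^2) & (r2 <= 55^2)) + 0L, 10, labels = TRUE)
  blob <- ((r2 <= 55^2) & (outer(x, x, function(a, b) a + 0.3 * b) > -10)) + 0L
  fixed <- section2d(blob, 10, labels = TRUE)
  idf <- register_affine2d(fixed, fixed)
  expect_equal(idf$scale_x, 1, tolerance = 0.01)
  expect_equal(idf$scale_y, 1, tolerance = 0.01)
  expect_equal(idf$rotation_deg, 0, tolerance = 0.5)

  shrink_mask <- function(m, sx, sy, th = 0) {
    c0 <- (n - 1) / 2
    xg <- matrix(seq_len(n) - 1, n, n); yg <- t(xg)
    ct <- cos(th * pi / 180); st <- sin(th * pi / 180)
    dx <- xg - c0; dy <- yg - c0
    mapx <- (ct * dx + st * dy) / sx + c0
    mapy <- (-st * dx + ct * dy) / sy + c0
    section2d((scafreg:::warp2d_cpp(unclass(m) + 0, mapx, mapy, 1L, 0) > 0.5) + 0L,
              10, labels = TRUE)
  }
  mv <- shrink_mask(fixed, 0.9, 0.8)
  fit <- register_affine2d(mv, fixed)       # maps fixed onto its shrunk copy
  expect_equal(fit$scale_x, 0.9, tolerance = 0.01)
  expect_equal(fit$scale_y, 0.8, tolerance = 0.01)

  rot <- shrink_mask(fixed, 1, 1, th = 15)
  fit_r <- register_affine2d(rot, fixed)
  expect_equal(abs(fit_r$rotation_deg), 15, tolerance = 0.5)
  expect_equal(fit_r$scale_x, 1, tolerance = 0.01)
  expect_equal(fit_r$scale_y, 1, tolerance = 0.01)
  expect_error(register_affine2d(section2d(matrix(0L, 20, 20), 10,
                                           labels = TRUE), fixed), "empty")
})
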