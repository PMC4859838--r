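# phantom module: scaffold voxelisation, tibia phantom, CT and histology
# simulators.

test_that("scaffold design invariants are enforced", {
  expect_error(scaffold_design(voxel_size_um = 60),
               "4 voxels")
  expect_error(scaffold_design(strut_diameter_um = 500,
                               lattice_pitch_um = 400),
               "smaller than lattice_pitch_um")
  expect_error(scaffold_design(diameter_mm = 0.5), "two lattice pitches")
  expect_error(scaffold_design(strut_diameter_um = 1e-9, voxel_size_um = 9),
               "4 voxels")
})

test_that("voxel-counted porosity agrees with the inclusion-exclusion oracle", {
  # analytic oracle computed independently here from the printed formulas:
  # 3 cylinders pi r^2 a, minus 3 Steinmetz 16 r^3/3, plus 8(2-sqrt 2) r^3
  d <- small_design()
  a <- d$lattice_pitch_um; r <- d$strut_diameter_um / 2
  v_union <- 3 * pi * r^2 * a - 16 * r^3 + 8 * (2 - sqrt(2)) * r^3
  oracle <- 1 - v_union / a^3
  expect_equal(analytic_scaffold_porosity(d), oracle, tolerance = 1e-12)
  s <- small_scaffold()
  # the small (1.6 mm) cylinder has strong clipping effects; the full-size
  # 2-point check is in the acceptance suite
  expect_lt(abs(s$porosity - oracle), 0.04)
  # roughness is radius-centred, so it barely moves the porosity
  s0 <- make_scaffold(small_design(roughness_um = 0))
  expect_lt(abs(s$porosity - s0$porosity), 0.02)
})

test_that("scaffold generation is reproducible and respects the cylinder", {
  s <- small_scaffold()
  s2 <- make_scaffold(small_design())
  expect_identical(as.vector(s$mask), as.vector(s2$mask))
  expect_true(all(as.vector(s$mask)[as.vector(s$cylinder) == 0L] == 0L))
})

test_that("tibia phantom trivial fills give exact BI/BC", {
  ph0 <- make_tibia_phantom(small_scaffold(), fill_fraction = 0,
                            seed = 1L, field_mm = 2.4)
  expect_equal(ph0$truth$true_BI_percent, 0)
  expect_equal(ph0$truth$true_BC_percent, 0)
  ph1 <- make_tibia_phantom(small_scaffold(), fill_fraction = 1,
                            contact_fraction = 1, seed = 1L, field_mm = 2.4)
  expect_equal(ph1$truth$true_BI_percent, 100)
  expect_equal(ph1$truth$true_BC_percent, 100)
  expect_error(make_tibia_phantom(small_scaffold(), fill_fraction = 0,
                                  contact_fraction = 0.5, field_mm = 2.4),
               "incompatible")
  expect_error(make_tibia_phantom(small_scaffold(), fill_fraction = 1.2),
               "\\[0, 1\\]")
})

test_that("phantom truth BI/BC are exactly recomputable via the quantify module", {
  ph <- small_phantom(fill = 0.5, edge_bias = 1)
  tr <- ph$truth
  expect_equal(bone_ingrowth(tr$bone_mask, tr$voi_mask, tr$scaffold_mask),
               tr$true_BI_percent, tolerance = 1e-12)
  expect_equal(bone_contact(tr$bone_mask, tr$scaffold_mask, tr$voi_mask),
               tr$true_BC_percent, tolerance = 1e-12)
  # achieved fill matches the requested fraction exactly by construction
  expect_equal(tr$true_BI_percent, 50, tolerance = 0.01)
})

test_that("edge-biased fill concentrates bone at the defect periphery", {
  ph <- small_phantom(fill = 0.5, edge_bias = 8)
  tr <- ph$truth
  prof <- bi_profile(tr$bone_mask, tr$voi_mask, tr$scaffold_mask, axis = 1)
  n <- nrow(prof)
  q <- floor(n / 4)
  outer_mean <- mean(prof$BI_percent[c(seq_len(q), (n - q + 1):n)])
  central_mean <- mean(prof$BI_percent[(q + 1):(n - q)])
  expect_gt(outer_mean, central_mean)
})

test_that("simulate_ct: identity forward model and determinism", {
  ph <- small_phantom()
  ct <- quiet_ct(ph$labels)
  lut <- c(20, 120, 60, 220, 120)
  expect_equal(as.vector(ct),
               lut[as.vector(ph$labels) + 1L], tolerance = 1e-12)
  p <- ct_sim_params(noise_sd = 5, streak_amplitude = 8, seed = 42L)
  expect_identical(as.vector(simulate_ct(ph$labels, p)),
                   as.vector(simulate_ct(ph$labels, p)))
  expect_error(ct_sim_params(titanium_intensity = 10),
               "titanium > bone > soft > background")
})

test_that("metal streaks concentrate near titanium", {
  ph <- small_phantom()
  clean <- quiet_ct(ph$labels, psf_sigma_um = 0)
  streaked <- quiet_ct(ph$labels, psf_sigma_um = 0, streak_amplitude = 15,
                       seed = 5L)
  err <- abs(as_plain(streaked) - as_plain(clean))
  ti <- as_plain(ph$truth$scaffold_mask) > 0
  near <- scafreg:::dilate_mask(ti, 3) & !ti
  far <- !scafreg:::dilate_mask(ti, 10)
  expect_gt(mean(err[near]), mean(err[far]))
})

test_that("extract_section reproduces stored slices and closed-form ramps", {
  ph <- small_phantom()
  ct <- quiet_ct(ph$labels)
  sp <- spacing_um(ct)
  d <- dim(ct)
  k <- 21L
  pose <- rigid_pose(c(0, 0, 0), c(0, 0, (k - 1 - (d[3] - 1) / 2) * sp))
  sec <- extract_section(ct, pose, thickness_um = sp)
  expect_equal(as.vector(sec), as.vector(as_array <- unclass(ct)[, , k]),
               tolerance = 1e-9)
  # averaging a z-constant volume over a thicker slab changes nothing
  flat <- vol3d(array(rep(unclass(ct)[, , k], 5), c(d[1], d[2], 5)), sp)
  s1 <- extract_section(flat, rigid_pose(), thickness_um = sp)
  s5 <- extract_section(flat, rigid_pose(), thickness_um = 5 * sp)
  expect_equal(as.vector(s1), as.vector(s5), tolerance = 1e-9)
  # oblique plane on a linear ramp: trilinear interpolation is exact and
  # slab-averaging of a linear field equals its central-plane value
  x <- (seq_len(40) - 1); ramp <- array(0, c(40, 40, 30))
  for (kk in 1:30) ramp[, , kk] <- outer(2 * x, 3 * x, "+") + 5 * (kk - 1)
  rv <- vol3d(ramp, 10)
  pose <- rigid_pose(c(8, 10, 0), c(15, -12, 7), thickness_um = 30)
  sec <- extract_section(rv, pose, out_size = c(12, 12))
  R <- euler_to_matrix(pose$euler_deg)
  ctr <- (dim(rv) - 1) / 2 * 10 + pose$translation_um
  expect_true(all(abs(sapply(1:12, function(i) sapply(1:12, function(j) {
    u <- (i - 6.5) * 10; v <- (j - 6.5) * 10
    p <- ctr + R %*% c(u, v, 0)
    (2 * p[1] + 3 * p[2] + 5 * p[3]) / 10 - unclass(sec)[i, j]
  }))) < 1e-6 * diff(range(ramp))))
})

test_that("extract_section rejects planes outside the volume", {
  ph <- small_phantom()
  ct <- quiet_ct(ph$labels)
  far <- rigid_pose(c(0, 0, 0), c(0, 0, 1e6))
  expect_error(extract_section(ct, far), "outside the volume")
})

test_that("simulate_histology identity deformation recolours the slab", {
  ph <- small_phantom()
  pose <- rigid_pose(c(0, 0, 0), c(0, 0, 0), 60)
  hp <- histology_sim_params(thickness_um = 60, shrink_x = 1, shrink_y = 1,
                             separation_um = 0, color_noise_sd = 0, seed = 3L)
  h <- simulate_histology(ph$labels, pose, hp, truth = ph$truth)
  # titanium mask identical to the CT-side slab titanium truth
  expect_identical(as.vector(h$labels2d == 3L),
                   as.vector(as_mask <- unclass(h$truth$slab_titanium) > 0))
  # colours are the exact stain colours
  cols <- unique(matrix(unclass(h$image), ncol = 3))
  ref <- rbind(hp$stain_color_background, hp$stain_color_bone,
               hp$stain_color_soft, hp$stain_color_titanium)
  expect_true(all(apply(cols, 1, function(cc)
    any(colSums(abs(t(ref) - cc)) < 1e-9))))
})

test_that("imposed shrink scales the bone area by shrink_x * shrink_y", {
  ph <- small_phantom(fill = 0.6)
  pose <- rigid_pose(c(0, 0, 0), c(0, 0, 0), 60)
  h0 <- simulate_histology(ph$labels, pose,
                           histology_sim_params(60, shrink_x = 1,
                                                shrink_y = 1, seed = 3L))
  h1 <- simulate_histology(ph$labels, pose,
                           histology_sim_params(60, shrink_x = 0.922,
                                                shrink_y = 0.922, seed = 3L))
  # measured on the cortical ring, which shrinks clear of the titanium
  # (new bone inside the lattice partly shrinks under the opaque struts)
  bone0 <- sum(unclass(h0$labels2d) == 1L)
  bone1 <- sum(unclass(h1$labels2d) == 1L)
  expect_equal(bone1 / bone0, 0.922^2, tolerance = 0.02)
  # titanium is pointwise invariant under the deformation (fiducial)
  expect_identical(as.vector(h0$labels2d == 3L),
                   as.vector(h1$labels2d == 3L))
})

test_that("interface separation removes bone next to titanium", {
  ph <- small_phantom(fill = 1)
  pose <- rigid_pose(c(0, 0, 0), c(0, 0, 0), 60)
  h0 <- simulate_histology(ph$labels, pose,
                           histology_sim_params(60, separation_um = 0,
                                                seed = 3L))
  h1 <- simulate_histology(ph$labels, pose,
                           histology_sim_params(60, separation_um = 30,
                                                seed = 3L))
  ti <- unclass(h0$labels2d) == 3L
  near_ti <- scafreg:::dilate_mask(ti) & !ti
  expect_lt(sum(unclass(h1$labels2d)[near_ti] == 4L),
            sum(unclass(h0$labels2d)[near_ti] == 4L))
  expect_error(histology_sim_params(shrink_x = 0), "\\(0, 1\\]")
  expect_error(histology_sim_params(shrink_x = 1.4), "\\(0, 1\\]")
})
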