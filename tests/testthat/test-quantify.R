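# quantify module: VOI, BI, BC, shrinkage, profiles, orientation sampling
# and the small-sample statistics utilities.

mk2d <- function(m, sp = 10) section2d(m + 0L, sp, labels = TRUE)

test_that("define_voi is the mask intersection", {
  sp <- 10
  a <- array(0L, c(8, 8, 4)); a[2:7, 2:7, ] <- 1L
  b <- array(0L, c(8, 8, 4)); b[4:8, 4:8, ] <- 1L
  leg <- vol3d(a, sp, labels = TRUE); cyl <- vol3d(b, sp, labels = TRUE)
  voi <- define_voi(leg, cyl)
  expect_equal(sum(unclass(voi)), sum(a & b))
  expect_lte(sum(unclass(voi)), min(sum(a), sum(b)))
  # containment: leg superset of cylinder means VOI = cylinder
  full <- vol3d(array(1L, c(8, 8, 4)), sp, labels = TRUE)
  expect_equal(as.vector(define_voi(full, cyl)), as.vector(b))
  disj <- vol3d(array(0L, c(8, 8, 4)), sp, labels = TRUE)
  expect_error(define_voi(leg, disj), "empty intersection")
})

test_that("bone ingrowth covers its trivial and exact cases", {
  sp <- 10
  roi <- array(0L, c(10, 10, 5)); roi[2:9, 2:9, ] <- 1L
  scaf <- array(0L, c(10, 10, 5)); scaf[5:6, 5:6, ] <- 1L
  void <- roi == 1L & scaf == 0L
  full_bone <- array(as.integer(void), dim(roi))
  m <- function(x) vol3d(x, sp, labels = TRUE)
  expect_equal(bone_ingrowth(m(full_bone), m(roi), m(scaf)), 100)
  expect_equal(bone_ingrowth(m(array(0L, dim(roi))), m(roi), m(scaf)), 0)
  # include_scaffold mode uses the whole ROI as denominator
  expect_equal(bone_ingrowth(m(full_bone), m(roi), m(scaf),
                             include_scaffold = TRUE),
               100 * sum(void) / sum(roi))
  expect_error(bone_ingrowth(m(full_bone), m(array(0L, dim(roi))), m(scaf)),
               "empty ROI")
  # phantom: BI equals the stored truth exactly
  ph <- small_phantom(fill = 0.5, edge_bias = 1)
  expect_equal(bone_ingrowth(ph$truth$bone_mask, ph$truth$voi_mask,
                             ph$truth$scaffold_mask),
               ph$truth$true_BI_percent, tolerance = 1e-12)
})

test_that("bone contact matches a hand-countable construction", {
  # 2D square strut 11x11 inside an all-ROI field: 40 surface pixels;
  # coating the left column and the top row covers 21 of them
  n <- 40
  scaf <- matrix(0L, n, n); scaf[10:20, 10:20] <- 1L
  bone <- matrix(0L, n, n)
  bone[9, 10:20] <- 1L      # left coating
  bone[10:20, 21] <- 1L     # top coating
  roi <- matrix(1L, n, n)
  bc <- bone_contact(mk2d(bone), mk2d(scaf), mk2d(roi))
  expect_equal(bc, 100 * 21 / 40, tolerance = 1e-12)
  # full coating and no coating
  expect_equal(bone_contact(mk2d(1L - scaf), mk2d(scaf), mk2d(roi)), 100)
  expect_equal(bone_contact(mk2d(matrix(0L, n, n)), mk2d(scaf), mk2d(roi)), 0)
  expect_error(bone_contact(mk2d(bone), mk2d(matrix(0L, n, n)), mk2d(roi)),
               "absent")
  # phantom: BC equals the stored truth exactly
  ph <- small_phantom(fill = 0.5, edge_bias = 1)
  expect_equal(bone_contact(ph$truth$bone_mask, ph$truth$scaffold_mask,
                            ph$truth$voi_mask),
               ph$truth$true_BC_percent, tolerance = 1e-12)
})

test_that("BI and BC are monotone under bone insertion", {
  set.seed(21)
  n <- 30
  scaf <- matrix(0L, n, n); scaf[14:17, 14:17] <- 1L
  roi <- matrix(1L, n, n)
  bone <- matrix(0L, n, n)
  bi_prev <- 0; bc_prev <- 0
  free <- which(scaf == 0L)
  for (step in 1:6) {
    bone[sample(free, 60)] <- 1L
    bi <- bone_ingrowth(mk2d(bone), mk2d(roi), mk2d(scaf))
    bc <- bone_contact(mk2d(bone), mk2d(scaf), mk2d(roi))
    expect_gte(bi, bi_prev); expect_gte(bc, bc_prev)
    bi_prev <- bi; bc_prev <- bc
  }
})

test_that("shrinkage variants agree and recover the imposed deformation", {
  # identical masks, identity affine
  n <- 120
  x <- seq_len(n) - (n + 1) / 2
  r2 <- outer(x^2, x^2, "+")
  ring <- mk2d((r2 >= 35^2 & r2 <= 50^2) + 0L)
  id_fit <- register_affine2d(ring, ring)
  s_id <- shrinkage(ring, ring, id_fit)
  expect_equal(s_id$area_ratio_percent, 100)
  expect_equal(s_id$scale_product_percent, 100, tolerance = 1)
  expect_equal(s_id$shrinkage_area_percent, 0)
  # direct formula: 85 vs 100 pixels
  a <- mk2d(matrix(c(rep(1L, 85), rep(0L, 15)), 10))
  b <- mk2d(matrix(c(rep(1L, 100), rep(0L, 0)), 10))
  expect_equal(shrinkage(a, b, id_fit)$area_ratio_percent, 85)
  expect_error(shrinkage(a, mk2d(matrix(0L, 10, 10)), id_fit), "empty")
  # pure-affine deformation: variants (a) and (b) agree within 2 points
  c0 <- (n - 1) / 2
  xg <- matrix(seq_len(n) - 1, n, n); yg <- t(xg)
  sx <- 0.922; sy <- 0.922
  shr <- (scafreg:::warp2d_cpp(unclass(ring) + 0, c0 + (xg - c0) / sx,
                               c0 + (yg - c0) / sy, 1L, 0) > 0.5) + 0L
  fit <- register_affine2d(mk2d(shr), ring)
  s <- shrinkage(mk2d(shr), ring, fit)
  expect_equal(s$scale_product_percent, 100 * sx * sy, tolerance = 2)
  expect_lt(abs(s$area_ratio_percent - s$scale_product_percent), 2)
})

test_that("the BI profile is consistent with the 3D value", {
  ph <- small_phantom(fill = 0.5, edge_bias = 1)
  tr <- ph$truth
  prof <- bi_profile(tr$bone_mask, tr$voi_mask, tr$scaffold_mask, axis = 3)
  bi3d <- bone_ingrowth(tr$bone_mask, tr$voi_mask, tr$scaffold_mask)
  # exact identity: 3D BI is the void-weighted mean of per-slice BI
  expect_equal(sum(prof$BI_percent * prof$void_voxels) / sum(prof$void_voxels),
               bi3d, tolerance = 1e-9)
  # uniform fill gives a flat profile; empty bone gives zeros
  roi <- array(1L, c(12, 12, 6))
  bone <- array(1L, c(12, 12, 6))
  scafv <- array(0L, c(12, 12, 6))
  m <- function(x) vol3d(x, 10, labels = TRUE)
  pf <- bi_profile(m(bone), m(roi), m(scafv), axis = 3)
  expect_true(all(pf$BI_percent == 100))
  p0 <- bi_profile(m(array(0L, dim(roi))), m(roi), m(scafv), axis = 3)
  expect_true(all(p0$BI_percent == 0))
  expect_error(bi_profile(m(bone), m(roi), m(scafv), axis = 5), "axis")
})

test_that("orientation sampling behaves under symmetry", {
  n <- 101                               # odd: rotation centre on a pixel
  x <- seq_len(n) - (n + 1) / 2
  r2 <- outer(x^2, x^2, "+")
  roi <- mk2d((r2 <= 45^2) + 0L)
  bone <- mk2d((r2 <= 30^2) + 0L)        # concentric: rotation-invariant
  scaf <- mk2d((r2 >= 38^2 & r2 <= 42^2) + 0L)
  est1 <- orientation_sampled_estimate(bone, scaf, roi, "BI",
                                       n_orientations = 1, seed = 2)
  expect_equal(est1$sd, 0)
  est <- orientation_sampled_estimate(bone, scaf, roi, "BI",
                                      n_orientations = 5, seed = 2)
  expect_lt(est$sd, 1)                   # resampling jitter only
  plain <- bone_ingrowth(bone, roi, scaf)
  expect_lt(abs(est$mean - plain), 2)
})

test_that("Mann-Whitney exact enumeration matches hand results", {
  r <- compare_groups(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$U, 0)
  expect_equal(r$p_value, 0.1, tolerance = 1e-12)
  same <- compare_groups(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p_value, 1)
  # rank-based: invariant under a monotone transform
  a <- c(2.3, 5.1, 0.4, 9); b <- c(1.1, 7.7, 3.3)
  expect_equal(compare_groups(a, b)$p_value,
               compare_groups(exp(a), exp(b))$p_value, tolerance = 1e-12)
  expect_error(compare_groups(numeric(0), b), "empty group")
  # large samples switch to the tie-corrected normal approximation and
  # stay close to the exact answer
  set.seed(4)
  x <- rnorm(12); y <- rnorm(12, 1)
  big <- compare_groups(x, y)
  expect_match(big$method, "normal")
  expect_equal(big$p_value,
               stats::wilcox.test(x, y, correct = TRUE)$p.value,
               tolerance = 0.05)
})

test_that("regression band matches the closed form", {
  x <- c(1, 2, 3, 4, 5, 6)
  fit <- regression_with_band(x, 2 * x)
  expect_equal(fit$slope, 2, tolerance = 1e-12)
  expect_equal(fit$r, 1, tolerance = 1e-12)
  expect_lt(max(fit$band$upper - fit$band$lower), 1e-9)
  set.seed(8)
  y <- 3 + 0.5 * x + rnorm(6, 0, 0.4)
  fit2 <- regression_with_band(x, y, at = mean(x))
  s <- fit2$sigma
  half <- qt(0.975, 4) * s * sqrt(1 / 6)
  expect_equal((fit2$band$upper - fit2$band$lower) / 2, half,
               tolerance = 1e-9)
  # permutation invariance
  perm <- sample(6)
  fit3 <- regression_with_band(x[perm], y[perm], at = mean(x))
  expect_equal(fit3$slope, fit2$slope, tolerance = 1e-12)
  expect_equal(fit3$band$fit, fit2$band$fit, tolerance = 1e-12)
  expect_error(regression_with_band(rep(1, 5), 1:5), "constant x")
})

test_that("metrics records validate their fields", {
  rec <- metrics_record("s1", 6, BI_percent = 61, BC_percent = 65,
                        source = "ct3d")
  expect_equal(rec$BI_percent, 61)
  expect_error(metrics_record("s1", 6, BI_percent = 130), "\\[0, 100\\]")
  expect_error(metrics_record("s1", 6, BI_percent = 50, BI_sd = -1), ">= 0")
})
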