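# filters module: histogram normalisation, anisotropic diffusion, global
# thresholding and metal-artefact compensation.

test_that("histogram normalisation is idempotent and self-referential", {
  # densely populated histogram (uniform data): self-normalisation is the
  # identity to within binning error.  Sparse tails (e.g. normal data)
  # collapse to bin resolution, which rank preservation still covers.
  set.seed(1)
  v <- vol3d(array(runif(20^3, 50, 150), c(20, 20, 20)), 10)
  ref <- reference_histogram(v)
  out <- normalize_histogram(v, ref)
  bin_w <- diff(ref$bin_edges[1:2])
  expect_lt(max(abs(as.vector(out) - as.vector(v))), 2 * bin_w)
  # already-matching volume stays put when normalised again
  out2 <- normalize_histogram(out, ref)
  expect_lt(max(abs(as.vector(out2) - as.vector(out))), 2 * bin_w)
  expect_error(normalize_histogram(vol3d(array(1, c(4, 4, 4)), 1), ref),
               "constant")
})

test_that("uniform-to-uniform quantile matching is the affine map", {
  set.seed(2)
  v <- vol3d(array(runif(30^3), c(30, 30, 30)), 10)
  ref <- reference_histogram(bin_edges = seq(10, 20, length.out = 257),
                             cumulative_mass = seq(0, 1, length.out = 257))
  out <- normalize_histogram(v, ref)
  expected <- 10 + 10 * as.vector(v)
  bin_w <- 10 / 256
  expect_lt(max(abs(as.vector(out) - expected)), 3 * bin_w)
})

test_that("histogram normalisation preserves voxel rank order", {
  for (seed in 1:3) {
    set.seed(seed)
    v <- vol3d(array(rnorm(12^3)^3, c(12, 12, 12)), 5)
    ref <- reference_histogram(bin_edges = seq(0, 255, length.out = 129),
                               cumulative_mass = c(0, sort(runif(127)), 1))
    out <- normalize_histogram(v, ref)
    expect_true(all(diff(as.vector(out)[order(as.vector(v))]) > -1e-12))
  }
})

test_that("diffusion: identity at 0 iterations, conservation, max principle", {
  set.seed(3)
  img <- section2d(matrix(runif(48 * 48, 0, 255), 48), 10)
  expect_identical(as.vector(anisotropic_diffusion(img, diffusion_params(0))),
                   as.vector(img))
  out <- anisotropic_diffusion(img, diffusion_params(iterations = 25))
  expect_lt(abs(mean(as.vector(out)) - mean(as.vector(img))) /
              mean(as.vector(img)), 1e-6)
  expect_gte(min(as.vector(out)), min(as.vector(img)) - 1e-9)
  expect_lte(max(as.vector(out)), max(as.vector(img)) + 1e-9)
  vol <- vol3d(array(runif(16^3, 0, 255), c(16, 16, 16)), 10)
  outv <- anisotropic_diffusion(vol, diffusion_params(iterations = 10))
  expect_lt(abs(mean(as.vector(outv)) - mean(as.vector(vol))) /
              mean(as.vector(vol)), 1e-6)
  expect_error(anisotropic_diffusion(img, diffusion_params(step = 0.3)),
               "stability bound")
  expect_error(anisotropic_diffusion(vol, diffusion_params(step = 0.2)),
               "stability bound")
})

test_that("large-kappa diffusion matches the heat-equation (Gaussian) oracle", {
  # smooth Gaussian blob: heat evolution for time t convolves with a
  # Gaussian of variance 2t, so the blob stays Gaussian with sigma^2 + 2t
  n <- 64
  x <- seq_len(n) - (n + 1) / 2
  s0 <- 8
  blob <- function(s) 100 * exp(-outer(x^2, x^2, "+") / (2 * s^2))
  img <- section2d(blob(s0), 10)
  iters <- 20; step <- 0.125
  out <- anisotropic_diffusion(img, diffusion_params(iterations = iters,
                                                     kappa = 1e9,
                                                     step = step))
  s1 <- sqrt(s0^2 + 2 * iters * step)
  expected <- (s0^2 / s1^2) * blob(s1)   # 2D mass-conserving amplitude
  rms <- sqrt(mean((as.vector(out) - expected)^2))
  expect_lt(rms / diff(range(img)), 0.01)
})

test_that("global thresholding: value method and degenerate cases", {
  img <- section2d(matrix(c(10, 200, 10, 200), 2), 5)
  m <- global_threshold(img, value = 100)
  expect_identical(as.vector(m), as.integer(as.vector(img) == 200))
  expect_identical(as.vector(global_threshold(img, value = 300)),
                   rep(0L, 4))
  m_dark <- global_threshold(img, value = 100, polarity = "dark")
  expect_identical(as.vector(m_dark), as.integer(as.vector(img) == 10))
})

test_that("peak_average thresholding separates titanium on simulated CT", {
  ph <- small_phantom()
  dices <- vapply(1:3, function(s) {
    ct <- quiet_ct(ph$labels, seed = 20L + s, noise_sd = 5,
                   psf_sigma_um = 10)
    m <- global_threshold(ct, method = "peak_average",
                          calibration = list(ct))
    dice(m, ph$truth$scaffold_mask)
  }, numeric(1))
  expect_true(all(dices >= 0.95))
  # unimodal histogram cannot be calibrated
  set.seed(9)
  flat <- vol3d(array(rnorm(20^3, 50, 2), c(20, 20, 20)), 5)
  expect_error(global_threshold(flat, method = "peak_average"),
               "unimodal")
})

test_that("metal-artefact correction honours its contract", {
  ph <- small_phantom()
  ti <- ph$truth$scaffold_mask
  ct <- quiet_ct(ph$labels, noise_sd = 0, psf_sigma_um = 0)
  # max_iter = 0 is the identity
  out0 <- metal_artifact_correction(ct, ti, band_um = 60, max_iter = 0)
  expect_identical(as.vector(out0), as.vector(ct))
  # voxels outside the band are never modified
  out <- metal_artifact_correction(ct, ti, band_um = 60, max_iter = 2,
                                   bone_threshold = 90)
  dist <- scafreg:::chamfer_distance_cpp(
    array(as.integer(as.vector(ti)), dim(ct)), dim(ct),
    rep(spacing_um(ct), 3))
  outside <- array(dist > 60, dim(ct))
  expect_identical(as.vector(out)[outside], as.vector(ct)[outside])
  # artefact-free input: the downstream bone mask is essentially unchanged
  peaks <- c(soft = 60, bone = 120, titanium = 220)
  b_raw <- segment_bone_ct(ct, ti, peaks = peaks, correction = NULL)
  b_cor <- segment_bone_ct(out, ti, peaks = peaks, correction = NULL)
  expect_gte(dice(b_cor, b_raw), 0.95)
  expect_error(metal_artifact_correction(ct, vol3d(array(0L, dim(ct)),
                                                   spacing_um(ct),
                                                   labels = TRUE)),
               "empty")
})
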