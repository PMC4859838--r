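# Shared fixtures, all generated in code.  The "small" world is a scaled
# phantom (1.6 mm scaffold, 20 um voxels) used wherever the full 3 mm /
# 9 um world of the acceptance suite is unnecessarily slow.

.fixtures <- new.env(parent = emptyenv())

small_design <- function(voxel_size_um = 20, roughness_um = 10) {
  scaffold_design(diameter_mm = 1.6, height_mm = 1.2,
                  strut_diameter_um = 180, lattice_pitch_um = 400,
                  voxel_size_um = voxel_size_um,
                  roughness_um = roughness_um)
}

small_scaffold <- function() {
  if (is.null(.fixtures$scaf)) .fixtures$scaf <- make_scaffold(small_design())
  .fixtures$scaf
}

small_phantom <- function(fill = 0.5, edge_bias = 0, seed = 7L, ...) {
  key <- paste0("ph_", fill, "_", edge_bias, "_", seed)
  if (is.null(.fixtures[[key]]))
    .fixtures[[key]] <- make_tibia_phantom(small_scaffold(), fill,
                                           edge_bias = edge_bias,
                                           seed = seed, field_mm = 2.4,
                                           z_margin_mm = 0.2, ...)
  .fixtures[[key]]
}

quiet_ct <- function(labels, seed = 11L, noise_sd = 0, psf_sigma_um = 0,
                     streak_amplitude = 0, ...) {
  simulate_ct(labels, ct_sim_params(noise_sd = noise_sd,
                                    psf_sigma_um = psf_sigma_um,
                                    streak_amplitude = streak_amplitude,
                                    seed = seed, ...))
}

# a seeded random grayscale image
rand_image <- function(n = 32, seed = 1) {
  set.seed(seed)
  matrix(runif(n * n), n, n)
}
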