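# Registration-accuracy validation harness: repeat-scan noise, scanning
# resolution and cutting-induced distortion, measured on a bare scaffold
# phantom (the physical experiment this emulates used an implant without
# tissue, cut at 80 degrees to the cylinder axis).

# titanium mask from a 2D micro-CT section: diffusion + Otsu + despeckle
section_titanium_mask <- function(sec, strut_diameter_um = 180) {
  f <- anisotropic_diffusion(sec, diffusion_params())
  m <- global_threshold(f, method = "otsu")
  sp <- spacing_um(sec)
  mm <- filter_components(m, min_vox = 0.5 * pi * (strut_diameter_um / 2)^2 / sp^2)
  section2d(mm + 0L, sp, labels = TRUE)
}

# in-plane anisotropic scaling of a 2D mask about its centre
scale_section_mask <- function(mask, sx, sy) {
  m <- as_plain(mask) + 0
  nu <- nrow(m); nv <- ncol(m)
  cx <- (nu - 1) / 2; cy <- (nv - 1) / 2
  xg <- matrix(seq_len(nu) - 1, nu, nv)
  yg <- matrix(seq_len(nv) - 1, nu, nv, byrow = TRUE)
  out <- warp2d_cpp(m, cx + (xg - cx) / sx, cy + (yg - cy) / sy, 1L, 0)
  section2d((out > 0.5) + 0L, spacing_um(mask), labels = TRUE)
}

#' Registration-accuracy validation harness
#'
#' Reproduces three accuracy experiments in silico on a bare-scaffold
#' phantom scanned twice with independent noise: (i) `repeat_noise` -
#' a section extracted from the repeat scan is registered to the reference
#' volume; (ii) `resolution` - the section is resampled at several pixel
#' sizes before registration; (iii) `cut_distortion` - the section mask is
#' anisotropically shrunk in-plane (emulating saw-cut distortion of the
#' sectioned implant) before registration.  The section plane is tilted
#' `tilt_deg` from transverse (a cut at `90 - tilt_deg` degrees to the
#' cylinder axis).  Registration refines from a deliberately perturbed
#' initial pose, isolating the per-scenario similarity loss from global
#' search robustness.
#'
#' @param design a [scaffold_design()].
#' @param ct_params a [ct_sim_params()] (its seed is the base seed).
#' @param scenarios subset of
#'   `c("repeat_noise", "resolution", "cut_distortion")`.
#' @param resolutions section pixel sizes (um) for the resolution scenario.
#' @param shrink_factor in-plane shrink for the cut-distortion scenario.
#' @param tilt_deg section tilt from transverse (degrees).
#' @param out_csv optional path: write the table as CSV.
#' @return `data.frame` with `scenario`, `resolution_um`, `shrink`,
#'   `final_C`, `trans_err_um`, `trans_err_vox`, `rot_err_deg`.
#' @export
validate_registration <- function(design = scaffold_design(),
                                  ct_params = ct_sim_params(),
                                  scenarios = c("repeat_noise", "resolution",
                                                "cut_distortion"),
                                  resolutions = c(2.5, 4.5, 9.0),
                                  shrink_factor = 0.92, tilt_deg = 10,
                                  out_csv = NULL) {
  scenarios <- match.arg(scenarios, several.ok = TRUE)
  scaf <- make_scaffold(design)
  sp <- design$voxel_size_um
  labels <- vol3d(as_plain(scaf$mask) * LAB[["titanium"]], sp, labels = TRUE)
  seed <- ct_params$seed
  p_ref <- ct_params; p_ref$seed <- seed + 1L
  p_rep <- ct_params; p_rep$seed <- seed + 2L
  ref <- simulate_ct(labels, p_ref)
  rep_scan <- simulate_ct(labels, p_rep)
  vmask <- segment_titanium_ct(ref, threshold = "peak_average",
                               strut_diameter_um = design$strut_diameter_um)
  rep_mask <- segment_titanium_ct(rep_scan, threshold = "peak_average",
                                  strut_diameter_um = design$strut_diameter_um)
  pose_true <- rigid_pose(c(30, tilt_deg, 0), c(0, 0, 0), thickness_um = sp)
  # deliberate in-plane initialisation error: 2 voxels, 2 degrees
  init <- compose_pose(pose_true, th = 2, du = 2 * sp, dv = 2 * sp)
  init$thickness_um <- sp

  one <- function(scenario, res, shrink) {
    # section numerically extracted from the processed + segmented repeat
    # scan, at the requested pixel size
    smask <- extract_section(rep_mask, pose_true, thickness_um = sp,
                             out_spacing = res,
                             out_size = round(dim(ref)[1:2] * sp / res),
                             interp = "nearest", reduce = "max")
    smask <- section2d((unclass(smask) > 0) + 0L, res, labels = TRUE)
    if (shrink < 1) smask <- scale_section_mask(smask, shrink, shrink)
    fit <- refine_rigid(smask, vmask, init, thickness_um = sp)
    pd <- pose_difference(fit$pose, pose_true)
    data.frame(scenario = scenario, resolution_um = res, shrink = shrink,
               final_C = fit$final_C, trans_err_um = pd$translation_um,
               trans_err_vox = pd$translation_um / sp,
               rot_err_deg = pd$rotation_deg, stringsAsFactors = FALSE)
  }
  rows <- list()
  if ("repeat_noise" %in% scenarios)
    rows <- c(rows, list(one("repeat_noise", sp, 1)))
  if ("resolution" %in% scenarios)
    for (res in resolutions)
      rows <- c(rows, list(one("resolution", res, 1)))
  if ("cut_distortion" %in% scenarios)
    for (s in shrink_factor)
      rows <- c(rows, list(one("cut_distortion", sp, s)))
  out <- do.call(rbind, rows)
  if (!is.null(out_csv)) write.csv(out, out_csv, row.names = FALSE)
  out
}

#' End-to-end registration accuracy over random section poses
#'
#' The full pipeline exercised repeatedly on one default phantom: a single
#' implanted-tibia phantom is built and CT-scanned once (seeded), the
#' titanium is segmented from the volume; then each trial draws a random
#' oblique section pose (in-plane rotation 0-360 deg, both tilts within
#' `tilt_max_deg`, in-plane offsets within 50 um, axial offset within
#' 400 um), simulates a stained histology section with shrinkage and
#' interface separation, segments its titanium, and registers it back
#' into the volume by coarse search plus rigid refinement.  Reported per
#' trial: final C and the pose error against the known ground truth.
#'
#' @param design a [scaffold_design()].
#' @param n_trials number of seeded trials.
#' @param seed base seed; all per-stage seeds derive from it.
#' @param fill_fraction,edge_bias phantom bone fill controls.
#' @param noise_sd CT noise SD (intensity range is 200 by default, so 10
#'   is 5 percent of range).
#' @param thickness_um,shrink,separation_um histology world controls.
#' @param tilt_max_deg maximum out-of-plane tilt of the random pose.
#' @param verbose emit one message per trial.
#' @return `data.frame` with `trial`, `final_C`, `trans_err_vox`,
#'   `rot_err_deg`, `evaluations`.
#' @export
registration_accuracy_trials <- function(design = scaffold_design(),
                                         n_trials = 20, seed = 1L,
                                         fill_fraction = 0.5, edge_bias = 1,
                                         noise_sd = 10, thickness_um = 60,
                                         shrink = 0.92, separation_um = 30,
                                         tilt_max_deg = 10,
                                         verbose = FALSE) {
  base <- (as.integer(seed) %% 1000000L) * 1000L
  sp <- design$voxel_size_um
  scaf <- make_scaffold(design)
  ph <- make_tibia_phantom(scaf, fill_fraction, edge_bias = edge_bias,
                           seed = base + 1L)
  labels <- ph$labels
  rm(scaf, ph)
  ct <- simulate_ct(labels, ct_sim_params(noise_sd = noise_sd,
                                          seed = base + 2L))
  vmask <- segment_titanium_ct(ct, threshold = "peak_average",
                               strut_diameter_um = design$strut_diameter_um)
  rm(ct)
  gc(verbose = FALSE)
  zmax <- min(400, design$height_mm * 500 - thickness_um)
  rows <- vector("list", n_trials)
  for (i in seq_len(n_trials)) {
    pose <- with_seed(base + 10L * i, {
      rigid_pose(c(runif(1, 0, 360), runif(1, -tilt_max_deg, tilt_max_deg),
                   runif(1, -tilt_max_deg, tilt_max_deg)),
                 c(runif(1, -50, 50), runif(1, -50, 50),
                   runif(1, -zmax, zmax)), thickness_um)
    })
    h <- simulate_histology(labels, pose,
                            histology_sim_params(thickness_um,
                                                 shrink_x = shrink,
                                                 shrink_y = shrink,
                                                 separation_um = separation_um,
                                                 seed = base + 10L * i + 1L))
    smask <- segment_titanium_histology(h$image,
                                        strut_diameter_um =
                                          design$strut_diameter_um)
    cand <- coarse_search(smask, vmask, search_grid(),
                          thickness_um = thickness_um)
    fit <- refine_rigid(smask, vmask, attr(cand, "poses")[[1]],
                        thickness_um = thickness_um)
    pd <- pose_difference(fit$pose, pose)
    rows[[i]] <- data.frame(trial = i, final_C = fit$final_C,
                            trans_err_vox = pd$translation_um / sp,
                            rot_err_deg = pd$rotation_deg,
                            evaluations = fit$evaluations)
    if (verbose)
      message(sprintf("trial %d: C = %.4f, err = %.2f vox / %.2f deg",
                      i, fit$final_C, pd$translation_um / sp,
                      pd$rotation_deg))
  }
  do.call(rbind, rows)
}
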