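# Histomorphometric quantification: VOI/ROI definition, bone ingrowth,
# bone-implant contact, shrinkage, edge-to-edge profiles, orientation
# sampling and summary statistics.

as_mask <- function(x) as_mask_fast(x)

#' Defect-equivalent volume of interest
#'
#' Voxelwise intersection of the (registered) average-leg-model mask and
#' the cylindrical mask matching the implant dimensions.
#'
#' @param leg_model_mask,cylinder_mask binary masks on the same grid.
#' @return binary `labelvol`.
#' @export
define_voi <- function(leg_model_mask, cylinder_mask) {
  if (!identical(dim(leg_model_mask), dim(cylinder_mask)))
    stop("define_voi: masks must share a grid")
  voi <- as_mask(leg_model_mask) & as_mask(cylinder_mask)
  if (!any(voi)) stop("define_voi: empty intersection")
  vol3d(voi + 0L, spacing_um(leg_model_mask), labels = TRUE)
}

#' Bone ingrowth (BI)
#'
#' `BI = 100 * |bone in ROI void| / |ROI void|`, where the ROI void
#' excludes the scaffold cross-section (so that a fully filled pore space
#' reads 100 %).  Set `include_scaffold = TRUE` to use the whole ROI as
#' the denominator instead.  Works for 2D areas and 3D volumes alike.
#'
#' @param bone_mask,roi_mask,scaffold_mask binary masks on a common grid.
#' @param include_scaffold keep the scaffold in the denominator.
#' @return percentage in \[0, 100\].
#' @export
bone_ingrowth <- function(bone_mask, roi_mask, scaffold_mask,
                          include_scaffold = FALSE) {
  bone <- as_mask(bone_mask); roi <- as_mask(roi_mask)
  scaf <- as_mask(scaffold_mask)
  denom_mask <- if (include_scaffold) roi else (roi & !scaf)
  n <- sum(denom_mask)
  if (n == 0) stop("bone_ingrowth: empty ROI")
  100 * sum(bone & denom_mask & !scaf) / n
}

# surface elements: mask voxels face-adjacent (6 in 3D, 4 in 2D) to
# non-mask voxels
surface_elements <- function(mask) {
  mask & dilate_mask(!mask)
}

#' Bone-implant contact (BC)
#'
#' `BC = 100 * (scaffold-surface elements with bone within band_voxels) /
#' (scaffold-surface elements within the ROI)`.  A surface element is a
#' scaffold voxel inside the ROI with a face neighbour that is
#' non-scaffold and also inside the ROI (the implant surface facing the
#' defect; the outer rim facing host tissue outside the ROI is excluded,
#' so a fully bone-filled defect reads 100 %).  With the default band of
#' one voxel, "contact" means bone in the face neighbourhood.
#'
#' @param bone_mask,scaffold_mask,roi_mask binary masks on a common grid.
#' @param band_voxels contact distance in voxels (default 1).
#' @return percentage in \[0, 100\].
#' @export
bone_contact <- function(bone_mask, scaffold_mask, roi_mask,
                         band_voxels = 1) {
  bone <- as_mask(bone_mask); scaf <- as_mask(scaffold_mask)
  roi <- as_mask(roi_mask)
  surf <- scaf & roi & dilate_mask(roi & !scaf)
  n <- sum(surf)
  if (n == 0) stop("bone_contact: scaffold absent from ROI")
  covered <- dilate_mask(bone, steps = band_voxels)  # city-block band
  100 * sum(surf & covered) / n
}

#' Histology shrinkage, two variants
#'
#' (a) area ratio: `100 * area(histology cortical bone) / area(2D micro-CT
#' cortical bone)`; (b) scale-factor product: `100 * scale_x * scale_y`
#' from the 2D affine registration.  Both retained-fraction ratios are
#' returned together with the corresponding shrinkage (`100 - ratio`).
#'
#' @param hist_mask,ct_mask binary cortical masks with equal pixel size.
#' @param affine an [register_affine2d()] result mapping the CT mask onto
#'   the histology mask.
#' @return list with `area_ratio_percent`, `scale_product_percent`,
#'   `shrinkage_area_percent`, `shrinkage_scale_percent`.
#' @export
shrinkage <- function(hist_mask, ct_mask, affine) {
  ct_area <- sum(as_mask(ct_mask))
  if (ct_area == 0) stop("shrinkage: empty CT cortical mask")
  if (abs(spacing_um(hist_mask) - spacing_um(ct_mask)) > 1e-9)
    stop("shrinkage: masks must share a pixel size")
  area_ratio <- 100 * sum(as_mask(hist_mask)) / ct_area
  scale_prod <- 100 * affine$scale_x * affine$scale_y
  list(area_ratio_percent = area_ratio,
       scale_product_percent = scale_prod,
       shrinkage_area_percent = 100 - area_ratio,
       shrinkage_scale_percent = 100 - scale_prod)
}

#' Edge-to-edge bone-ingrowth profile
#'
#' Void-referenced BI per slice along a chosen axis, restricted to the
#' VOI; positions are slice centres in micrometres.  Slices whose VOI void
#' is empty are dropped.
#'
#' @param bone_mask,voi_mask,scaffold_mask binary 3D masks.
#' @param axis 1 (x), 2 (y) or 3 (z).
#' @return `data.frame` with `position_um`, `BI_percent`, `void_voxels`.
#' @export
bi_profile <- function(bone_mask, voi_mask, scaffold_mask, axis = 1) {
  if (!axis %in% 1:3) stop("bi_profile: axis must be 1, 2 or 3")
  bone <- as_mask(bone_mask); voi <- as_mask(voi_mask)
  scaf <- as_mask(scaffold_mask)
  sp <- spacing_um(voi_mask)
  void <- voi & !scaf
  num <- apply(bone & void, axis, sum)
  den <- apply(void, axis, sum)
  keep <- den > 0
  data.frame(position_um = (which(keep) - 1) * sp,
             BI_percent = 100 * num[keep] / den[keep],
             void_voxels = den[keep])
}

#' Orientation-sampled metric estimate
#'
#' Re-measures BI or BC after rotating the measurement grid by `n`
#' random in-plane angles (nearest-neighbour mask resampling about the ROI
#' centroid), mirroring manual grid-based histomorphometry repeated over
#' random orientations; returns the mean and SD across orientations.
#'
#' @param bone_mask,scaffold_mask,roi_mask binary 2D masks.
#' @param metric `"BI"` or `"BC"`.
#' @param n_orientations number of random orientations (>= 1).
#' @param seed RNG seed.
#' @param band_voxels passed to [bone_contact()].
#' @return list with `mean`, `sd`, `values`, `angles_deg`.
#' @export
orientation_sampled_estimate <- function(bone_mask, scaffold_mask, roi_mask,
                                         metric = c("BI", "BC"),
                                         n_orientations = 5, seed = 1L,
                                         band_voxels = 1) {
  metric <- match.arg(metric)
  if (n_orientations < 1) stop("orientation_sampled_estimate: n_orientations >= 1")
  sp <- spacing_um(roi_mask)
  roi <- as_mask(roi_mask)
  ci <- colMeans(which(roi, arr.ind = TRUE)) - 1
  nu <- nrow(roi); nv <- ncol(roi)
  xg <- matrix(seq_len(nu) - 1, nu, nv)
  yg <- matrix(seq_len(nv) - 1, nu, nv, byrow = TRUE)
  rot_mask <- function(m, th) {
    ct <- cos(th); st <- sin(th)
    dx <- xg - ci[1]; dy <- yg - ci[2]
    mapx <- ct * dx - st * dy + ci[1]
    mapy <- st * dx + ct * dy + ci[2]
    warp2d_cpp(as_plain(m) + 0, mapx, mapy, 1L, 0) > 0.5
  }
  angles <- with_seed(seed, runif(n_orientations, 0, 2 * pi))
  vals <- vapply(angles, function(th) {
    b <- section2d(rot_mask(bone_mask, th) + 0L, sp, labels = TRUE)
    s <- section2d(rot_mask(scaffold_mask, th) + 0L, sp, labels = TRUE)
    r <- section2d(rot_mask(roi_mask, th) + 0L, sp, labels = TRUE)
    if (metric == "BI") bone_ingrowth(b, r, s)
    else bone_contact(b, s, r, band_voxels = band_voxels)
  }, numeric(1))
  list(mean = mean(vals), sd = if (length(vals) > 1) sd(vals) else 0,
       values = vals, angles_deg = angles * 180 / pi)
}

#' Metrics record
#'
#' One specimen/timepoint/source row of the quantification table.
#'
#' @param specimen_id text identifier.
#' @param timepoint_weeks numeric time point.
#' @param BI_percent,BC_percent percentages in \[0, 100\].
#' @param BI_sd,BC_sd nonnegative standard deviations.
#' @param shrinkage_area_percent,shrinkage_scale_percent shrinkage values.
#' @param source one of `"histology"`, `"ct2d"`, `"ct3d"`.
#' @return one-row `data.frame`.
#' @export
metrics_record <- function(specimen_id, timepoint_weeks = NA_real_,
                           BI_percent = NA_real_, BC_percent = NA_real_,
                           BI_sd = 0, BC_sd = 0,
                           shrinkage_area_percent = NA_real_,
                           shrinkage_scale_percent = NA_real_,
                           source = c("histology", "ct2d", "ct3d")) {
  source <- match.arg(source)
  for (p in c(BI_percent, BC_percent))
    if (!is.na(p) && (p < 0 || p > 100))
      stop("metrics_record: percentages must lie in [0, 100]")
  if (BI_sd < 0 || BC_sd < 0) stop("metrics_record: SDs must be >= 0")
  data.frame(specimen_id = specimen_id, timepoint_weeks = timepoint_weeks,
             BI_percent = BI_percent, BI_sd = BI_sd,
             BC_percent = BC_percent, BC_sd = BC_sd,
             shrinkage_area_percent = shrinkage_area_percent,
             shrinkage_scale_percent = shrinkage_scale_percent,
             source = source, stringsAsFactors = FALSE)
}
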