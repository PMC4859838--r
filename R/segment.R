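# Titanium and bone segmentation from micro-CT volumes and RGB histology.

# keep connected components with at least `min_vox` voxels (face
# connectivity); `keep_largest` always retains the largest component.
filter_components <- function(mask, min_vox = 0, keep_largest = TRUE) {
  d <- dim(mask)
  dim3 <- if (length(d) == 2L) c(d, 1L) else d
  m <- as_plain(mask)
  if (!is.integer(m)) m <- as.integer(m != 0)
  dim(m) <- dim3
  lab <- label_components_cpp(m, as.integer(dim3))
  sizes <- tabulate(lab)
  if (!length(sizes)) return(array(FALSE, d))
  keep <- which(sizes >= min_vox)
  if (keep_largest) keep <- union(keep, which.max(sizes))
  array(lab %in% keep, d)   # keep ids are >= 1, so background stays FALSE
}

#' Segment titanium from a micro-CT volume
#'
#' Anisotropic diffusion, then global thresholding (bright polarity), then
#' connected-component despeckling: components smaller than half the
#' expected single-strut cross-section are dropped (the largest component
#' is always retained).
#'
#' @param vol intensity `vol3d`.
#' @param diffusion a [diffusion_params()].
#' @param threshold passed to [global_threshold()]: either a numeric value
#'   or a method name (`"peak_average"`, `"otsu"`).
#' @param calibration calibration volumes for `"peak_average"`.
#' @param strut_diameter_um expected strut diameter, for the component-size
#'   floor.
#' @return binary `labelvol` titanium mask.
#' @export
segment_titanium_ct <- function(vol, diffusion = diffusion_params(),
                                threshold = "peak_average",
                                calibration = NULL,
                                strut_diameter_um = 180) {
  stopifnot(inherits(vol, "vol3d"))
  sp <- spacing_um(vol)
  f <- anisotropic_diffusion(vol, diffusion)
  m <- if (is.numeric(threshold))
    global_threshold(f, value = threshold)
  else global_threshold(f, method = threshold, calibration = calibration)
  strut_area_vox <- pi * (strut_diameter_um / 2)^2 / sp^2
  mm <- filter_components(m, min_vox = 0.5 * strut_area_vox)
  if (!any(mm)) stop("segment_titanium_ct: no titanium found")
  vol3d(mm + 0L, sp, labels = TRUE)
}

#' Segment bone from a micro-CT volume
#'
#' Applies [metal_artifact_correction()] around the titanium, then
#' bone-window thresholding: bone is `[midpoint(soft, bone),
#' midpoint(bone, titanium))` from calibration class peaks.  The result
#' never overlaps the titanium mask.
#'
#' @param vol intensity `vol3d`.
#' @param titanium_mask binary mask from [segment_titanium_ct()].
#' @param window length-2 numeric `c(lo, hi)` bone window; or `NULL` to
#'   derive it from `peaks`.
#' @param peaks optional named class intensities
#'   (`soft`, `bone`, `titanium`) used to build the window.
#' @param correction list of arguments for [metal_artifact_correction()],
#'   or `NULL` to skip correction.
#' @return binary `labelvol` bone mask.
#' @export
segment_bone_ct <- function(vol, titanium_mask, window = NULL, peaks = NULL,
                            correction = list()) {
  stopifnot(inherits(vol, "vol3d"))
  if (!identical(dim(vol), dim(titanium_mask)))
    stop("segment_bone_ct: titanium mask must share the volume grid")
  if (is.null(window)) {
    if (is.null(peaks))
      stop("segment_bone_ct: supply a bone window or class peaks")
    window <- c((peaks[["soft"]] + peaks[["bone"]]) / 2,
                (peaks[["bone"]] + peaks[["titanium"]]) / 2)
  }
  if (window[1] >= window[2])
    stop("segment_bone_ct: thresholds out of order (lo >= hi)")
  if (!is.null(correction)) {
    args <- c(list(vol = vol, titanium_mask = titanium_mask,
                   bone_threshold = window[1]), correction)
    vol <- do.call(metal_artifact_correction, args)
  }
  v <- as_plain(vol)
  m <- v >= window[1] & v < window[2] & !(as_plain(titanium_mask) > 0)
  vol3d(m + 0L, spacing_um(vol), labels = TRUE)
}

#' Segment titanium from an RGB histology section
#'
#' Uses the red channel only (superior brightness/contrast for this stain),
#' smooths it with anisotropic diffusion, then thresholds.  In brightfield
#' ground sections the opaque titanium is the darkest class, so the
#' threshold selects the low tail.  Components smaller than half the
#' expected strut cross-section are dropped.
#'
#' @param rgb RGB `section2d`.
#' @param diffusion a [diffusion_params()].
#' @param threshold numeric value or method (default Otsu).
#' @param strut_diameter_um expected strut diameter for despeckling.
#' @return binary `section2d` mask.
#' @export
segment_titanium_histology <- function(rgb, diffusion = diffusion_params(),
                                       threshold = "otsu",
                                       strut_diameter_um = 180) {
  if (!inherits(rgb, "section2d") || !is_rgb(rgb))
    stop("segment_titanium_histology: input must be a 3-channel RGB section")
  sp <- spacing_um(rgb)
  red <- section2d(as_plain(rgb)[, , 1], sp)
  if (diff(range(as_plain(red))) == 0)        # blank field: nothing to find
    return(section2d(array(0L, dim(red)), sp, labels = TRUE))
  f <- anisotropic_diffusion(red, diffusion)
  m <- if (is.numeric(threshold)) global_threshold(f, value = threshold,
                                                   polarity = "dark")
  else global_threshold(f, method = threshold, polarity = "dark")
  strut_area_px <- pi * (strut_diameter_um / 2)^2 / sp^2
  mm <- filter_components(m, min_vox = 0.5 * strut_area_px)
  section2d(mm + 0L, sp, labels = TRUE)
}

#' Segment bone from an RGB histology section by stain colour
#'
#' Nearest-reference-colour classification after intensity normalisation:
#' both the image and the reference colours are scaled to unit mean
#' brightness, so the classification is invariant under a global intensity
#' gain.
#'
#' @param rgb RGB `section2d`.
#' @param stain_model named list of reference RGB triples; must contain
#'   `bone` and typically `soft`, `titanium`, `background` (a
#'   [histology_sim_params()] is accepted).
#' @return binary `section2d` bone mask.
#' @export
segment_bone_histology <- function(rgb, stain_model) {
  if (!inherits(rgb, "section2d") || !is_rgb(rgb))
    stop("segment_bone_histology: input must be a 3-channel RGB section")
  if (missing(stain_model) || is.null(stain_model))
    stop("segment_bone_histology: a stain model with reference colours is required")
  if (inherits(stain_model, "histology_sim_params"))
    stain_model <- list(bone = stain_model$stain_color_bone,
                        soft = stain_model$stain_color_soft,
                        titanium = stain_model$stain_color_titanium,
                        background = stain_model$stain_color_background)
  if (is.null(stain_model$bone))
    stop("segment_bone_histology: stain model must name a 'bone' colour")
  sp <- spacing_um(rgb)
  a <- as_plain(rgb)
  d <- dim(a)
  px <- matrix(a, d[1] * d[2], 3)
  # normalise to the brightest material (background/resin in brightfield)
  # so a global intensity gain cancels exactly
  px_n <- px / max(quantile(rowMeans(px), 0.99), 1e-12)
  refs <- do.call(rbind, stain_model)
  refs_n <- refs / max(rowMeans(refs))
  d2 <- sapply(seq_len(nrow(refs_n)), function(r)
    rowSums((px_n - matrix(refs_n[r, ], nrow(px_n), 3, byrow = TRUE))^2))
  cls <- max.col(-d2, ties.method = "first")
  bone <- matrix(cls == which(rownames(refs) == "bone"), d[1], d[2])
  section2d(bone + 0L, sp, labels = TRUE)
}
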